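# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no enumerate_diplotypes / em_frequencies /
# lbl_mcmc internals) so they can serve as cross-checks.

# Brute force: all unordered haplotype pairs over w SNPs compatible with a
# complete dosage vector, by scanning all 2^w x 2^w ordered pairs.
brute_pairs <- function(g) {
  w <- length(g)
  out <- list()
  for (h1 in 0:(2^w - 1)) {
    for (h2 in h1:(2^w - 1)) {
      a1 <- as.integer(intToBits(h1))[w:1]
      a2 <- as.integer(intToBits(h2))[w:1]
      if (all(a1 + a2 == g)) out[[length(out) + 1L]] <- c(h1, h2)
    }
  }
  do.call(rbind, out)
}

# Per-individual compatible pair sets for two-locus data (haplotype codes
# 0..3 over the 2 SNPs), via brute force.
two_locus_pairsets <- function(dosage) {
  lapply(seq_len(nrow(dosage)),
         function(i) brute_pairs(as.integer(dosage[i, ])) + 1L)
}

# Observed-data log-likelihood of two-locus genotype data as a function of
# the four haplotype frequencies (00, 01, 10, 11), phase marginalized.
two_locus_loglik <- function(f, dosage, pairsets = two_locus_pairsets(dosage)) {
  sum(vapply(pairsets, function(prs) {
    k <- prs[, 1]; l <- prs[, 2]
    log(sum(ifelse(k == l, f[k]^2, 2 * f[k] * f[l])))
  }, numeric(1)))
}

# Dense grid search over the 3-simplex for the two-locus MLE (step 0.01),
# vectorized over grid points.
two_locus_grid_mle <- function(dosage, step = 0.01) {
  s <- seq(0, 1, step)
  grid <- expand.grid(f1 = s, f2 = s, f3 = s)
  grid <- grid[grid$f1 + grid$f2 + grid$f3 <= 1 + 1e-12, ]
  fm <- cbind(grid$f1, grid$f2, grid$f3,
              pmax(1 - grid$f1 - grid$f2 - grid$f3, 0))
  fm <- pmax(fm, 1e-12)
  pairsets <- two_locus_pairsets(dosage)
  ll <- rep(0, nrow(fm))
  for (prs in pairsets) {
    k <- prs[, 1]; l <- prs[, 2]
    p <- rep(0, nrow(fm))
    for (r in seq_along(k)) {
      p <- p + if (k[r] == l[r]) fm[, k[r]]^2 else 2 * fm[, k[r]] * fm[, l[r]]
    }
    ll <- ll + log(p)
  }
  best <- which.max(ll)
  list(f = unname(fm[best, ]), loglik = ll[best])
}

# Exact retrospective log-likelihood for phase-known data, written
# independently of the sampler. Parameters: intercept a, coefficients b
# (per non-baseline haplotype), frequencies f, HWD d.
retro_loglik <- function(a, b, f, d, k1, k2, y) {
  K <- length(f)
  bfull <- c(0, b)
  pz <- function(k, l) if (k == l) d * f[k] + (1 - d) * f[k]^2 else
    2 * (1 - d) * f[k] * f[l]
  py <- function(yv, k, l) {
    lp <- a + bfull[k] + bfull[l]
    if (yv == 1) stats::plogis(lp) else 1 - stats::plogis(lp)
  }
  th <- c(0, 0)
  for (k in 1:K) for (l in k:K) {
    th[1] <- th[1] + pz(k, l) * py(0, k, l)
    th[2] <- th[2] + pz(k, l) * py(1, k, l)
  }
  s <- 0
  for (i in seq_along(y)) {
    s <- s + log(py(y[i], k1[i], k2[i])) + log(pz(k1[i], k2[i])) -
      log(th[y[i] + 1])
  }
  s
}

# Batch-means Monte Carlo standard error of a chain's mean.
batch_mcse <- function(x, n_batch = 30) {
  m <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(b) mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  stats::sd(means) / sqrt(n_batch)
}

# Monte-Carlo marginal prior tail Pr(|beta| > eps) under the Bayesian-LASSO
# prior: lambda ~ Gamma(a, b), beta | lambda ~ DoubleExponential(0, lambda).
mc_prior_tail <- function(eps, a, b, n = 1e6, seed = 1) {
  set.seed(seed)
  lam <- stats::rgamma(n, a, rate = b)
  # |beta| | lambda ~ Exp(lambda)
  mean(stats::rexp(n, rate = lam) > eps)
}

# Small helper: binary label vector from a simulated cohort's truth.
truth_y <- function(sim) as.integer(sim$truth$status == "CASE")
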