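#' Expected haplotype copy counts given genotypes and frequencies
#'
#' For each kept individual, the posterior expectation (under Hardy-Weinberg
#' proportions at the supplied frequencies, trait ignored) of the number of
#' copies of each haplotype carried: the score-test design matrix.
#'
#' @param exp A [enumerate_diplotypes()] expansion.
#' @param hf A [em_frequencies()] fit on the same expansion.
#' @return Numeric matrix, kept individuals x haplotypes (columns in
#'   `hf$label` order).
#' @export
expected_hap_counts <- function(exp, hf) {
  idx <- index_expansion(exp, hf)
  f <- hf$freq
  pz <- ifelse(idx$k1 == idx$k2, f[idx$k1]^2, 2 * f[idx$k1] * f[idx$k2])
  denom <- rowsum_vec(pz, idx$i, idx$n)
  w <- pz / denom[idx$i]
  K <- length(f)
  e <- matrix(0, idx$n, K, dimnames = list(NULL, hf$label))
  for (k in seq_len(K)) {
    e[, k] <- rowsum_vec(w * ((idx$k1 == k) + (idx$k2 == k)), idx$i, idx$n)
  }
  e
}

#' Haplotype score test of case-control association
#'
#' Haplotype frequencies are estimated by EM independently of the trait; per
#' individual the expected copy count `e_ih` of each haplotype is formed,
#' and the score vector `U_h = sum_i (y_i - ybar) e_ih` is tested against
#' its empirical null variance
#' `V = sum_i (y_i - ybar)^2 (e_i - ebar)(e_i - ebar)'`. Each haplotype gets
#' a two-sided normal test of `z_h = U_h / sqrt(V_hh)`; the global statistic
#' `U' V^- U` (generalized inverse) is chi-squared on `rank(V)` degrees of
#' freedom.
#'
#' @param exp A [enumerate_diplotypes()] expansion.
#' @param y Binary labels (1 = case) aligned with kept individuals.
#' @param hf Optional [em_frequencies()] fit (computed when `NULL`).
#' @param alpha Significance level for the per-haplotype flag; default 0.05.
#' @return List with `haplotypes` (tibble: `hap`, `freq`, `score`,
#'   `statistic` (z), `p_value`, `significant`) and `global` (list
#'   `statistic`, `df`, `p_value`, `significant`), plus `n_used`.
#' @export
score_test <- function(exp, y, hf = NULL, alpha = 0.05) {
  if (is.null(hf)) hf <- em_frequencies(exp)
  y <- as.integer(y)
  n <- length(exp$pairs)
  if (length(y) != n) stop("y must align with kept individuals")
  e <- expected_hap_counts(exp, hf)
  yc <- y - mean(y)
  U <- as.numeric(crossprod(e, yc))
  ec <- sweep(e, 2, colMeans(e))
  V <- crossprod(ec * abs(yc), ec * abs(yc))  # sum yc_i^2 (e-ebar)(e-ebar)'
  vd <- diag(V)
  z <- ifelse(vd > 1e-12, U / sqrt(vd), 0)
  p <- ifelse(vd > 1e-12, 2 * stats::pnorm(-abs(z)), 1)
  rk <- qr(V)$rank
  if (rk == 0L) {
    warning("no variation in expected haplotype counts; p = 1")
    glob <- list(statistic = 0, df = 0L, p_value = 1, significant = FALSE)
  } else {
    stat <- as.numeric(t(U) %*% MASS::ginv(V) %*% U)
    glob <- list(statistic = stat, df = rk,
                 p_value = stats::pchisq(stat, rk, lower.tail = FALSE))
    glob$significant <- glob$p_value < alpha
  }
  list(haplotypes = tibble::tibble(hap = hf$label, freq = hf$freq,
                                   score = U, statistic = z, p_value = p,
                                   significant = p < alpha),
       global = glob, n_used = n)
}

#' EM-GLM haplotype association with pooling (Wald tests)
#'
#' Prospective-likelihood analogue of haplo.glm/hapassoc: haplotype
#' frequencies and logistic regression coefficients are estimated jointly by
#' EM over pseudo-individuals (one per compatible diplotype), with weights
#' proportional to `P(y | pair, beta) * P(pair | f)`. The design uses copy
#' counts of each non-baseline haplotype (baseline = most frequent);
#' haplotypes with frequency below the pooling tolerance are merged into a
#' single POOLED column, which participates in the fit but is never declared
#' a significant haplotype. Standard errors come from the inverse observed
#' information of the joint likelihood (regression block, numerical
#' Hessian); Wald p-values are two-sided normal.
#'
#' @param exp A [enumerate_diplotypes()] expansion.
#' @param y Binary labels (1 = case) aligned with kept individuals.
#' @param tolerance Pooling tolerance: haplotype frequency below which
#'   haplotypes are pooled. Profile `"glm"` enforces a minimum of 0.001;
#'   profile `"hapassoc"` allows 0 (every haplotype modeled individually).
#' @param profile `"hapassoc"` (default) or `"glm"`.
#' @param alpha Significance level; default 0.05.
#' @param tol Convergence tolerance on the log-likelihood gain (1e-6).
#' @param max_iter EM iteration cap (200). Non-convergence is reported, not
#'   ignored: a non-converged fit carries no p-values or significance flags.
#' @return List of class `glm_em_fit`: `haplotypes` tibble (`hap`, `freq`,
#'   `estimate`, `se`, `statistic`, `p_value`, `significant`, `pooled`),
#'   `converged`, `reason`, `loglik`, `baseline`, `n_used`.
#' @export
glm_em_fit <- function(exp, y, tolerance = 0, profile = c("hapassoc", "glm"),
                       alpha = 0.05, tol = 1e-6, max_iter = 200) {
  profile <- match.arg(profile)
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  if (profile == "glm") tolerance <- max(tolerance, 0.001)
  y <- as.integer(y)
  n <- length(exp$pairs)
  if (length(y) != n) stop("y must align with kept individuals")
  hf <- em_frequencies(exp)
  idx <- index_expansion(exp, hf)
  K <- length(hf$freq)
  if (K < 2L) stop("no contrast: only one haplotype in the window")

  pooled <- hf$freq < tolerance
  pooled[1] <- FALSE  # baseline never pooled
  design_haps <- which(!pooled)[-1]  # non-baseline, unpooled
  cnt <- function(k) (idx$k1 == k) + (idx$k2 == k)
  X <- vapply(design_haps, cnt, numeric(length(idx$i)))
  if (length(design_haps) == 0L) X <- matrix(0, length(idx$i), 0)
  cols <- hf$label[design_haps]
  if (any(pooled)) {
    pc <- rowSums(vapply(which(pooled), cnt, numeric(length(idx$i))))
    X <- cbind(X, pc)
    cols <- c(cols, "POOLED")
  }
  X <- cbind(`(Intercept)` = 1, X)
  colnames(X) <- c("(Intercept)", cols)
  yl <- y[idx$i]

  f <- hf$freq
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  reason <- "max_iter"
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    py <- ifelse(yl == 1L, stats::plogis(eta), 1 - stats::plogis(eta))
    pz <- ifelse(idx$k1 == idx$k2, f[idx$k1]^2, 2 * f[idx$k1] * f[idx$k2])
    joint <- py * pz
    denom <- rowsum_vec(joint, idx$i, idx$n)
    ll <- sum(log(denom))
    w <- joint / denom[idx$i]
    fit <- suppressWarnings(
      stats::glm.fit(X, yl, weights = w, family = stats::binomial(),
                     control = stats::glm.control(maxit = 50)))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    f <- vapply(seq_len(K), function(k)
      sum(w * ((idx$k1 == k) + (idx$k2 == k))), numeric(1)) / (2 * idx$n)
    # hapassoc-style fits flag separation as non-convergence; the glm
    # profile (mirroring haplo.glm) lets the likelihood plateau and reports
    # the resulting large-coefficient, large-SE Wald tests
    if (profile == "hapassoc" && max(abs(beta), na.rm = TRUE) > 15) {
      reason <- "separation"
      break
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      reason <- NA_character_
      break
    }
    ll_old <- ll
  }

  se <- rep(NA_real_, ncol(X))
  if (converged) {
    if (profile == "glm") {
      # haplo.glm-style: complete-data (weighted IRLS) covariance from the
      # final M-step. This ignores phase and frequency uncertainty and is
      # anti-conservative for rare haplotypes — deliberately mirroring the
      # comparator's documented behavior.
      mu <- stats::plogis(as.numeric(X %*% beta))
      info <- crossprod(X * sqrt(w * mu * (1 - mu)))
      cv <- try(solve(info), silent = TRUE)
    } else {
      # hapassoc-style improved SEs: regression block of the inverse
      # observed information of the joint likelihood
      H <- try(obs_information(X, yl, idx, K, beta, f), silent = TRUE)
      cv <- if (inherits(H, "try-error")) H else try(solve(H), silent = TRUE)
    }
    if (inherits(cv, "try-error") || any(diag(cv)[seq_len(ncol(X))] <= 0)) {
      converged <- FALSE
      reason <- "singular_information"
    } else {
      se <- sqrt(diag(cv)[seq_len(ncol(X))])
    }
  }

  est <- beta[-1]
  se_h <- se[-1]
  zstat <- if (converged) est / se_h else rep(NA_real_, length(est))
  pval <- if (converged) 2 * stats::pnorm(-abs(zstat)) else
    rep(NA_real_, length(est))
  is_pooled <- cols == "POOLED"
  haps <- tibble::tibble(
    hap = cols,
    freq = c(hf$freq[design_haps],
             if (any(pooled)) sum(hf$freq[pooled]) else NULL),
    estimate = est, se = se_h, statistic = zstat, p_value = pval,
    significant = if (converged) (pval < alpha) & !is_pooled else
      rep(NA, length(est)),
    pooled = is_pooled)
  structure(list(haplotypes = haps, converged = converged, reason = reason,
                 loglik = ll, baseline = hf$label[1], f = f, hf = hf,
                 profile = profile, tolerance = tolerance, n_used = n),
            class = "glm_em_fit")
}

## Numerical observed information (central differences) of the joint
## observed-data log-likelihood in (beta, eta) with f = softmax(c(0, eta));
## the most frequent haplotype is the softmax reference so the log-ratio
## parameterization stays well scaled for rare haplotypes. Frequencies that
## have collapsed to numerical zero are held fixed (their curvature is zero
## and would make the information matrix singular without affecting the
## regression-block standard errors).
obs_information <- function(X, yl, idx, K, beta, f, h = 1e-3) {
  live <- which(f[-1] >= 1e-6) + 1L  # frequencies estimated, hap 1 reference
  eta_full <- log(pmax(f, 1e-300) / f[1])
  th0 <- c(beta, eta_full[live])
  q <- length(th0)
  nb <- length(beta)
  ll <- function(th) {
    b <- th[seq_len(nb)]
    eta <- eta_full
    eta[live] <- th[-seq_len(nb)]
    ef <- exp(eta - max(eta))
    fv <- ef / sum(ef)
    lin <- as.numeric(X %*% b)
    py <- ifelse(yl == 1L, stats::plogis(lin), 1 - stats::plogis(lin))
    pz <- ifelse(idx$k1 == idx$k2, fv[idx$k1]^2, 2 * fv[idx$k1] * fv[idx$k2])
    sum(log(rowsum_vec(py * pz, idx$i, idx$n)))
  }
  hs <- h * pmax(1, abs(th0))
  H <- matrix(0, q, q)
  f0 <- ll(th0)
  for (i in seq_len(q)) {
    for (j in i:q) {
      ei <- ej <- numeric(q)
      ei[i] <- hs[i]; ej[j] <- hs[j]
      if (i == j) {
        H[i, i] <- (ll(th0 + ei) - 2 * f0 + ll(th0 - ei)) / hs[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (ll(th0 + ei + ej) - ll(th0 + ei - ej) -
             ll(th0 - ei + ej) + ll(th0 - ei - ej)) / (4 * hs[i] * hs[j])
      }
    }
  }
  -H
}

#' Single-SNP logistic association scan
#'
#' Per SNP, logistic regression of case-control status on minor-allele
#' dosage (individuals missing that SNP dropped), with a Wald test of the
#' dosage coefficient. Monomorphic SNPs yield `NA` and are excluded from the
#' significant set.
#'
#' @param g A filtered [genotype_matrix()].
#' @param y Binary labels (1 = case) aligned with `g`'s samples.
#' @param alpha First-stage significance level; default 0.05.
#' @return Tibble with `snp_id`, `position`, `estimate`, `p_value`,
#'   `significant`.
#' @export
single_snp_scan <- function(g, y, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  y <- as.integer(y)
  out <- lapply(seq_len(ncol(g$dosage)), function(j) {
    x <- g$dosage[, j]
    ok <- !is.na(x)
    xs <- x[ok]; ys <- y[ok]
    if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) {
      return(c(NA_real_, NA_real_))
    }
    fit <- suppressWarnings(stats::glm(ys ~ xs, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2L) return(c(NA_real_, NA_real_))
    c(cf[2, 1], cf[2, 4])
  })
  est <- vapply(out, `[`, numeric(1), 1)
  p <- vapply(out, `[`, numeric(1), 2)
  tibble::tibble(snp_id = g$snp_ids, position = g$positions,
                 estimate = est, p_value = p,
                 significant = !is.na(p) & p < alpha)
}
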