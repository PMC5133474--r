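#' Diplotype probability under a frequency model with Hardy-Weinberg
#' disequilibrium
#'
#' For haplotype frequencies `f` and excess-homozygosity parameter `d`, the
#' probability of the unordered haplotype pair (k, l) is
#' `2 (1 - d) f_k f_l` for k != l and `d f_k + (1 - d) f_k^2` for k == l;
#' `d = 0` recovers Hardy-Weinberg equilibrium and `d = 1` complete
#' homozygosity. All diplotype probabilities are non-negative iff
#' `d > d_min = -min_k f_k / (1 - f_k)`; probabilities over all unordered
#' pairs sum to one.
#'
#' @param k,l Indices into `f` (unordered pair; vectors recycle).
#' @param f Frequency vector (non-negative, sums to 1).
#' @param d HWD parameter in `(d_min, 1]`.
#' @return Numeric vector of pair probabilities.
#' @export
diplotype_probability <- function(k, l, f, d = 0) {
  if (any(k < 1 | k > length(f) | l < 1 | l > length(f)))
    stop("pair index outside haplotype list")
  if (d > 1 || d <= hwd_lower_bound(f))
    stop("d outside admissible range")
  ifelse(k == l, d * f[k] + (1 - d) * f[k]^2, 2 * (1 - d) * f[k] * f[l])
}

#' Lower bound of the admissible HWD parameter range
#' @param f Frequency vector.
#' @return `-min(f) / (1 - min(f))`, the infimum of admissible `d`.
#' @export
hwd_lower_bound <- function(f) {
  fm <- min(f)
  -fm / (1 - fm)
}

#' Estimate haplotype frequencies by EM from a diplotype expansion
#'
#' Standard EM for unphased genotypes under Hardy-Weinberg equilibrium
#' (`d` fixed at 0): the E-step weights each individual's compatible pairs
#' by their current diplotype probabilities, the M-step sets each frequency
#' to its expected allele-pair count over `2n`. The log-likelihood is
#' non-decreasing across iterations; the run stops when the gain falls below
#' `tol` or after `max_iter` iterations (flagged as non-converged).
#' Starting frequencies count every compatible pair of an individual equally.
#'
#' Phase ambiguity makes many haplotypes compatible with some genotype even
#' though they are absent from the sample; EM drives their frequencies to
#' numerical zero. Haplotypes whose converged frequency falls below
#' `zero_tol` are removed from the list (frequencies renormalized), so
#' downstream models are built only on haplotypes with non-negligible
#' estimated frequency.
#'
#' @param exp A [enumerate_diplotypes()] expansion with at least one kept
#'   individual.
#' @param tol Convergence tolerance on the log-likelihood gain; default 1e-8.
#' @param max_iter Iteration cap; default 1000.
#' @param zero_tol Frequency below which a haplotype is dropped from the
#'   final list; default 1e-8.
#' @return An object of class `hap_freq`: list with `hap` (integer codes,
#'   sorted by decreasing frequency, ties broken by binary string), `label`
#'   (binary strings), `freq`, `d` (0), `width`, `loglik` (trace),
#'   `converged`, `n` (individuals used).
#' @export
em_frequencies <- function(exp, tol = 1e-8, max_iter = 1000,
                           zero_tol = 1e-8) {
  stopifnot(inherits(exp, "diplotype_expansion"))
  if (length(exp$pairs) == 0L) stop("no non-dropped individuals")
  lf <- expansion_long(exp)
  haps <- sort(unique(c(lf$h1, lf$h2)))
  K <- length(haps)
  k1 <- match(lf$h1, haps)
  k2 <- match(lf$h2, haps)
  n <- lf$n
  grp <- lf$i

  # equal weight per compatible pair within an individual
  w0 <- 1 / tabulate(grp, n)[grp]
  f <- (rowsum_vec(w0, k1, K) + rowsum_vec(w0, k2, K)) / (2 * n)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pz <- ifelse(k1 == k2, f[k1]^2, 2 * f[k1] * f[k2])
    denom <- rowsum_vec(pz, grp, n)
    ll <- sum(log(denom))
    ll_trace <- c(ll_trace, ll)
    w <- pz / denom[grp]
    f <- (rowsum_vec(w, k1, K) + rowsum_vec(w, k2, K)) / (2 * n)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }

  keep <- f >= zero_tol
  haps <- haps[keep]
  f <- f[keep] / sum(f[keep])
  lab <- hap_string(haps, exp$width)
  ord <- order(-f, lab)
  structure(
    list(hap = haps[ord], label = lab[ord], freq = as.numeric(f[ord]),
         d = 0, width = exp$width, loglik = ll_trace,
         converged = converged, n = n),
    class = "hap_freq"
  )
}

#' @export
print.hap_freq <- function(x, ...) {
  cat(sprintf("hap_freq: %d haplotypes over %d SNPs (n = %d, %s)\n",
              length(x$freq), x$width, x$n,
              if (x$converged) "EM converged" else "EM NOT converged"))
  print(utils::head(tibble::tibble(hap = x$label, freq = x$freq), 12))
  invisible(x)
}

## sum of x by integer group id (1..K); dense, NA-free
rowsum_vec <- function(x, g, K) {
  out <- numeric(K)
  s <- rowsum(x, g)   # drops absent groups; rebuild dense
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

## Per-individual pair indices into hf order. Pairs containing a haplotype
## pruned from the frequency list are dropped; every individual must retain
## at least one compatible pair (guaranteed for EM-based pruning, since each
## individual places posterior weight ~1/|pairs| on its best pair).
index_expansion <- function(exp, hf) {
  lf <- expansion_long(exp)
  k1 <- match(lf$h1, hf$hap)
  k2 <- match(lf$h2, hf$hap)
  ok <- !is.na(k1) & !is.na(k2)
  i <- lf$i[ok]
  if (length(unique(i)) != lf$n)
    stop("pruning the haplotype list left an individual with no compatible pair")
  list(i = i, k1 = k1[ok], k2 = k2[ok], n = lf$n)
}
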