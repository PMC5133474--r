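#' Permute case-control labels
#'
#' Uniform random permutation of the label vector, destroying any
#' genotype-phenotype association while preserving the case and control
#' counts. Reproducible given the seed.
#'
#' @param labels Vector of labels (binary or `"CASE"`/`"CONTROL"`).
#' @param seed Integer seed.
#' @return The permuted labels (same type as input).
#' @export
permute_phenotypes <- function(labels, seed = 1) {
  set.seed(seed)
  labels[sample.int(length(labels))]
}

#' Per-method false-positive summary of a scan report
#'
#' For each method, the denominator is the total number of haplotypes
#' reported across all windows of the gene and the numerator the number
#' found significant among them; non-converged results are excluded from
#' both. The score overall test is summarized separately with windows as
#' the denominator, and the single-SNP scan with SNPs as the denominator.
#' Applied to a scan of permuted (or otherwise null) labels this estimates
#' the per-method false-positive proportion.
#'
#' @param report A [run_scan()] report (typically on permuted labels).
#' @return Tibble with `method`, `n_reported`, `n_significant`,
#'   `proportion` (`NA` when nothing was reported).
#' @export
fpr_summary <- function(report) {
  stopifnot(inherits(report, "scan_report"))
  res <- report$results
  res <- res[res$converged & !is.na(res$significant), , drop = FALSE]
  methods <- unique(res$method)
  out <- lapply(methods, function(m) {
    r <- res[res$method == m, , drop = FALSE]
    n_rep <- nrow(r)
    n_sig <- sum(r$significant)
    tibble::tibble(method = m, n_reported = n_rep, n_significant = n_sig,
                   proportion = if (n_rep > 0) n_sig / n_rep else NA_real_)
  })
  if (length(out) == 0L) {
    return(tibble::tibble(method = character(0), n_reported = integer(0),
                          n_significant = integer(0), proportion = numeric(0)))
  }
  do.call(rbind, out)
}

#' Permutation-based false-positive assessment
#'
#' Repeats: permute the case-control labels, rerun the sliding-window scan,
#' summarize per-method significant/reported proportions. Defaults to a
#' single permutation; with `R > 1` the per-permutation rows are returned
#' together with per-method means.
#'
#' @param g A filtered [genotype_matrix()].
#' @param status Case-control labels (EXCLUDED individuals are not
#'   permuted or analyzed).
#' @param R Number of permutations; default 1.
#' @param seed Integer seed; permutation r uses `seed + r - 1`.
#' @param ... Passed to [run_scan()] (methods, width, controls, ...).
#' @return List with `per_permutation` (tibble with `permutation` column)
#'   and `mean` (per-method mean proportion over permutations).
#' @export
permutation_fpr <- function(g, status, R = 1, seed = 1, ...) {
  y <- status_to_y(status)
  keep <- !is.na(y)
  gk <- genotype_matrix(g$dosage[keep, , drop = FALSE],
                        sample_ids = g$sample_ids[keep],
                        snp_ids = g$snp_ids, positions = g$positions,
                        flipped = g$flipped)
  y <- y[keep]
  rows <- lapply(seq_len(R), function(r) {
    yp <- permute_phenotypes(y, seed = seed + r - 1L)
    rep_r <- run_scan(gk, yp, seed = seed + r - 1L, ...)
    s <- fpr_summary(rep_r)
    s$permutation <- r
    s
  })
  per <- do.call(rbind, rows)
  agg <- stats::aggregate(proportion ~ method, data = per, FUN = mean,
                          na.rm = TRUE, na.action = stats::na.pass)
  list(per_permutation = per, mean = tibble::as_tibble(agg))
}
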