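#' Sliding windows over retained SNPs
#'
#' Overlapping windows of `width` consecutive SNPs stepped by one SNP:
#' `n_snps - width + 1` windows when `n_snps >= width`, otherwise none
#' (with a warning).
#'
#' @param n_snps Number of retained SNPs.
#' @param width Window width in SNPs; default 5.
#' @return Tibble with columns `window`, `start`, `end` (1-based inclusive
#'   indices over retained SNPs).
#' @export
make_windows <- function(n_snps, width = 5) {
  if (width < 1) stop("width must be >= 1")
  if (n_snps < width) {
    warning(sprintf("fewer SNPs (%d) than window width (%d): no windows",
                    n_snps, width))
    return(tibble::tibble(window = integer(0), start = integer(0),
                          end = integer(0)))
  }
  start <- seq_len(n_snps - width + 1L)
  tibble::tibble(window = start, start = start, end = start + width - 1L)
}

#' Gene-wide sliding-window haplotype association scan
#'
#' For each window: enumerate compatible diplotypes (window-local
#' missingness, so the excluded individuals are recomputed per window),
#' estimate haplotype frequencies by EM, and run the requested methods. A
#' failure in one window (e.g. a window with no haplotype contrast) is
#' logged and does not abort the scan. Per-window seeds are derived
#' deterministically from the global seed and the window start, so results
#' do not depend on execution order.
#'
#' @param g A filtered, recoded [genotype_matrix()].
#' @param status Case-control labels aligned with `g`'s samples: a vector of
#'   `"CASE"`/`"CONTROL"`/`"EXCLUDED"` (see [derive_status()]) or binary
#'   0/1. EXCLUDED individuals are dropped.
#' @param methods Subset of `c("lbl", "score", "glm", "hapassoc",
#'   "single_snp")`.
#' @param width Window width; default 5.
#' @param gene Gene identifier carried into the report.
#' @param lbl_ctrl [lbl_control()] list for the LBL fits.
#' @param glm_tolerance Pooling tolerance for the `"glm"` profile (floored
#'   at 0.001) ; `hapassoc_tolerance` for the `"hapassoc"` profile
#'   (default 0).
#' @param hapassoc_tolerance See above.
#' @param alpha Frequentist significance level; default 0.05.
#' @param seed Global seed; default 1.
#' @return An object of class `scan_report`: list with `gene`, `windows`
#'   (window table with bp locations), `results` (tibble: one row per
#'   haplotype per window per method, plus `(overall)` rows for the score
#'   global test and per-SNP rows for `single_snp`), `totals` (per-method
#'   reported/significant counts), `failures` (tibble `window`, `method`,
#'   `error`), `n_case`, `n_control`.
#' @export
run_scan <- function(g, status, methods = c("lbl", "score", "glm"),
                     width = 5, gene = "gene",
                     lbl_ctrl = lbl_control(),
                     glm_tolerance = 0.001, hapassoc_tolerance = 0,
                     alpha = 0.05, seed = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  methods <- match.arg(methods,
                       c("lbl", "score", "glm", "hapassoc", "single_snp"),
                       several.ok = TRUE)
  y_all <- status_to_y(status)
  keep <- !is.na(y_all)
  dos <- g$dosage[keep, , drop = FALSE]
  y_all <- y_all[keep]
  win <- make_windows(ncol(dos), width)
  win$loc_start <- g$positions[win$start]
  win$loc_end <- g$positions[win$end]

  res <- list()
  fails <- list()
  hap_methods <- setdiff(methods, "single_snp")
  for (wi in seq_len(nrow(win))) {
    idx <- win$start[wi]:win$end[wi]
    exp <- enumerate_diplotypes(dos[, idx, drop = FALSE])
    y <- y_all[exp$kept]
    wseed <- window_seed(seed, win$start[wi])
    base <- tibble::tibble(window = win$window[wi],
                           loc_start = win$loc_start[wi],
                           loc_end = win$loc_end[wi])
    hf <- NULL
    for (m in hap_methods) {
      r <- tryCatch({
        if (length(y) == 0L) stop("all individuals dropped in window")
        if (is.null(hf)) hf <- em_frequencies(exp)
        rows <- switch(
          m,
          lbl = {
            fit <- lbl_fit(exp, y, start = hf, control = lbl_ctrl,
                           seed = wseed)
            s <- fit$summary
            tibble::tibble(base, method = "lbl", hap = s$hap, freq = s$freq,
                           estimate = s$beta_mean, OR = s$OR,
                           statistic = NA_real_, p_value = NA_real_,
                           bf = s$bf, significant = s$significant,
                           converged = TRUE, n_used = fit$n_used)
          },
          score = {
            st <- score_test(exp, y, hf = hf, alpha = alpha)
            h <- st$haplotypes
            rbind(
              tibble::tibble(base, method = "score", hap = h$hap,
                             freq = h$freq, estimate = NA_real_,
                             OR = NA_real_, statistic = h$statistic,
                             p_value = h$p_value, bf = NA_real_,
                             significant = h$significant, converged = TRUE,
                             n_used = st$n_used),
              tibble::tibble(base, method = "score_global",
                             hap = "(overall)", freq = NA_real_,
                             estimate = NA_real_, OR = NA_real_,
                             statistic = st$global$statistic,
                             p_value = st$global$p_value, bf = NA_real_,
                             significant = st$global$significant,
                             converged = TRUE, n_used = st$n_used))
          },
          glm = ,
          hapassoc = {
            tolr <- if (m == "glm") glm_tolerance else hapassoc_tolerance
            fit <- glm_em_fit(exp, y, tolerance = tolr,
                              profile = if (m == "glm") "glm" else "hapassoc",
                              alpha = alpha)
            h <- fit$haplotypes
            tibble::tibble(base, method = m, hap = h$hap, freq = h$freq,
                           estimate = h$estimate, OR = exp(h$estimate),
                           statistic = h$statistic, p_value = h$p_value,
                           bf = NA_real_, significant = h$significant,
                           converged = fit$converged, n_used = fit$n_used)
          })
        rows
      }, error = function(e) e)
      if (inherits(r, "error")) {
        fails[[length(fails) + 1L]] <-
          tibble::tibble(window = win$window[wi], method = m,
                         error = conditionMessage(r))
      } else {
        res[[length(res) + 1L]] <- r
      }
    }
  }
  if ("single_snp" %in% methods) {
    gk <- genotype_matrix(dos, snp_ids = g$snp_ids, positions = g$positions,
                          flipped = g$flipped)
    ss <- single_snp_scan(gk, y_all, alpha = alpha)
    res[[length(res) + 1L]] <-
      tibble::tibble(window = NA_integer_, loc_start = ss$position,
                     loc_end = ss$position, method = "single_snp",
                     hap = ss$snp_id, freq = NA_real_,
                     estimate = ss$estimate, OR = exp(ss$estimate),
                     statistic = NA_real_, p_value = ss$p_value,
                     bf = NA_real_, significant = ss$significant,
                     converged = TRUE, n_used = length(y_all))
  }
  results <- if (length(res)) do.call(rbind, res) else
    tibble::tibble(window = integer(0), loc_start = integer(0),
                   loc_end = integer(0), method = character(0),
                   hap = character(0), freq = numeric(0),
                   estimate = numeric(0), OR = numeric(0),
                   statistic = numeric(0), p_value = numeric(0),
                   bf = numeric(0), significant = logical(0),
                   converged = logical(0), n_used = integer(0))
  if (nrow(win) == 0L) warning("zero windows: empty report")
  structure(
    list(gene = gene, windows = win, results = results,
         totals = report_totals(results),
         failures = if (length(fails)) do.call(rbind, fails) else
           tibble::tibble(window = integer(0), method = character(0),
                          error = character(0)),
         n_case = sum(y_all == 1L), n_control = sum(y_all == 0L),
         seed = seed),
    class = "scan_report"
  )
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("scan_report: gene %s, %d windows, %d cases / %d controls\n",
              x$gene, nrow(x$windows), x$n_case, x$n_control))
  print(x$totals)
  if (nrow(x$failures)) {
    cat(sprintf("%d window/method failures\n", nrow(x$failures)))
  }
  invisible(x)
}

report_totals <- function(results) {
  conv <- results[results$converged, , drop = FALSE]
  if (nrow(conv) == 0L) {
    return(tibble::tibble(method = character(0), n_reported = integer(0),
                          n_significant = integer(0)))
  }
  agg <- stats::aggregate(
    cbind(n_reported = rep(1L, nrow(conv)),
          n_significant = as.integer(conv$significant %in% TRUE)) ~ method,
    data = data.frame(method = conv$method,
                      significant = conv$significant), FUN = sum)
  tibble::as_tibble(agg)
}

status_to_y <- function(status) {
  if (is.numeric(status) || is.logical(status)) {
    y <- as.integer(status)
    if (!all(y %in% c(0L, 1L, NA_integer_))) stop("numeric status must be 0/1")
    return(y)
  }
  s <- toupper(as.character(status))
  ifelse(s == "CASE", 1L, ifelse(s == "CONTROL", 0L, NA_integer_))
}

## deterministic per-window seed below 2^31
window_seed <- function(seed, start) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(start) * 104729) %%
               2147483629)
}
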