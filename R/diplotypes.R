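#' @useDynLib rhapscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Convert haplotype integer codes to binary allele strings
#'
#' Haplotypes over a window of `width` SNPs are stored internally as the
#' integer whose base-2 digits are the allele vector (first SNP = most
#' significant bit), so code 21 with width 5 is `"10101"`.
#'
#' @param code Integer vector of haplotype codes.
#' @param width Window width (number of SNPs).
#' @return Character vector of 0/1 strings of length `width`.
#' @export
hap_string <- function(code, width) {
  vapply(code, function(x) {
    paste(as.integer(bitwAnd(bitwShiftR(x, (width - 1):0), 1L)), collapse = "")
  }, character(1))
}

#' Convert binary allele strings to haplotype integer codes
#' @param s Character vector of 0/1 strings (all the same length).
#' @return Integer vector of codes (see [hap_string()]).
#' @export
hap_code <- function(s) {
  vapply(strsplit(s, ""), function(b) {
    sum(as.integer(b) * 2L^(rev(seq_along(b)) - 1L))
  }, numeric(1)) |> as.integer()
}

#' Allele-count matrix for haplotype codes
#' @param code Integer haplotype codes.
#' @param width Window width.
#' @return Integer matrix, one row per code, one 0/1 column per SNP.
#' @export
hap_alleles <- function(code, width) {
  m <- vapply(seq_len(width),
              function(j) bitwAnd(bitwShiftR(code, width - j), 1L),
              integer(length(code)))
  matrix(m, nrow = length(code), dimnames = list(NULL, NULL))
}

## Unordered pairs (canonical: first <= second) compatible with one complete
## dosage vector; returns a 2-column integer matrix of codes.
pairs_for_complete <- function(g) {
  w <- length(g)
  base <- sum((g == 2L) * 2L^(rev(seq_len(w)) - 1L))
  het <- which(g == 1L)
  h <- length(het)
  if (h == 0L) return(matrix(as.integer(base), 1, 2))
  bits <- 2L^(w - het)
  out <- matrix(0L, 2L^(h - 1L), 2L)
  for (m in 0:(2L^(h - 1L) - 1L)) {
    assign <- c(0L, as.integer(bitwAnd(bitwShiftR(m, (h - 2):0), 1L)))
    if (h == 1L) assign <- 0L
    h1 <- base + sum(bits * assign)
    h2 <- base + sum(bits * (1L - assign))
    out[m + 1L, ] <- c(min(h1, h2), max(h1, h2))
  }
  out
}

#' Enumerate diplotypes compatible with unphased window genotypes
#'
#' For each individual, lists all unordered haplotype pairs whose allele-wise
#' sum reproduces the observed dosages. An individual with `h` heterozygous
#' SNPs and no missing genotypes has `max(1, 2^(h-1))` compatible pairs. An
#' individual with exactly one missing genotype is expanded over the three
#' possible dosages at that SNP (the union of the resulting pair sets);
#' individuals with two or more missing genotypes are dropped, with the
#' reason recorded.
#'
#' @param dosage Matrix of window dosages (samples x SNPs, entries
#'   0/1/2/`NA`) or a [genotype_matrix()].
#' @param max_missing Maximum number of missing genotypes an individual may
#'   have and still be expanded; default 1 (the hapassoc-style rule). Set to
#'   0 for strict exclusion of any individual with a missing genotype.
#' @return An object of class `diplotype_expansion`: list with `width`,
#'   `sample_ids`, `pairs` (per kept individual, a 2-column matrix of
#'   haplotype codes), `kept` (logical), `dropped` (tibble `sample_id`,
#'   `reason`).
#' @export
enumerate_diplotypes <- function(dosage, max_missing = 1L) {
  if (inherits(dosage, "genotype_matrix")) dosage <- dosage$dosage
  dosage <- as.matrix(dosage)
  w <- ncol(dosage)
  if (w < 1L) stop("window width must be >= 1")
  n <- nrow(dosage)
  ids <- rownames(dosage) %||% paste0("S", seq_len(n))
  pairs <- vector("list", n)
  kept <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- dosage[i, ]
    nmiss <- sum(is.na(g))
    if (nmiss > max_missing) {
      kept[i] <- FALSE
      reason[i] <- if (nmiss == w) "all_genotypes_missing"
                   else sprintf("%d_missing_genotypes", nmiss)
      next
    }
    if (nmiss == 0L) {
      pairs[[i]] <- pairs_for_complete(as.integer(g))
    } else {
      j <- which(is.na(g))
      acc <- do.call(rbind, lapply(0:2, function(v) {
        g2 <- g; g2[j] <- v
        pairs_for_complete(as.integer(g2))
      }))
      pairs[[i]] <- acc[!duplicated(acc), , drop = FALSE]
    }
  }
  structure(
    list(width = w, sample_ids = ids, pairs = pairs[kept],
         kept = kept,
         dropped = tibble::tibble(sample_id = ids[!kept],
                                  reason = reason[!kept])),
    class = "diplotype_expansion"
  )
}

#' @export
print.diplotype_expansion <- function(x, ...) {
  cat(sprintf("diplotype_expansion: width %d, %d kept, %d dropped\n",
              x$width, length(x$pairs), nrow(x$dropped)))
  invisible(x)
}

## Long-format pair table: one row per (individual, compatible pair), with
## haplotype codes. Used by the EM, the score test and the EM-GLM.
expansion_long <- function(exp) {
  np <- vapply(exp$pairs, nrow, integer(1))
  tab <- do.call(rbind, exp$pairs)
  list(i = rep(seq_along(exp$pairs), np), h1 = tab[, 1], h2 = tab[, 2],
       n = length(exp$pairs))
}
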