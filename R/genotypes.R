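#' Construct a genotype matrix of minor-allele dosages
#'
#' The central genotype container: an individuals-by-SNP matrix of
#' minor-allele dosages in \{0, 1, 2, NA\} together with SNP identifiers and
#' base-pair positions. Positions must be strictly increasing within the
#' region (SNPs are assumed ordered along the gene).
#'
#' @param dosage Numeric or integer matrix, samples in rows, SNPs in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   rownames of `dosage`).
#' @param snp_ids Character vector of SNP identifiers (defaults to colnames).
#' @param positions Integer vector of 1-based base-pair positions, strictly
#'   increasing. Defaults to `seq_len(ncol(dosage))`.
#' @param flipped Logical vector marking SNPs whose alleles were swapped by
#'   [recode_minor()]; defaults to all `FALSE`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `sample_ids`, `snp_ids`, `positions`, `flipped`.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            snp_ids = colnames(dosage),
                            positions = seq_len(ncol(dosage)),
                            flipped = rep(FALSE, ncol(dosage))) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosage)))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  positions <- as.integer(positions)
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (length(sample_ids) != nrow(dosage))
    stop("sample_ids length does not match number of rows")
  if (length(snp_ids) != ncol(dosage))
    stop("snp_ids length does not match number of columns")
  if (length(positions) != ncol(dosage))
    stop("positions length does not match number of columns")
  if (ncol(dosage) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (anyDuplicated(snp_ids)) stop("duplicated snp_ids")
  dimnames(dosage) <- list(sample_ids, snp_ids)
  structure(
    list(dosage = dosage, sample_ids = sample_ids, snp_ids = snp_ids,
         positions = positions, flipped = as.logical(flipped)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  positions %s..%s; %d SNP(s) allele-flipped; %.1f%% missing\n",
              format(min(x$positions)), format(max(x$positions)),
              sum(x$flipped), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Per-SNP minor-allele frequency
#'
#' MAF is computed over non-missing genotypes only. For a column that has
#' already been recoded so that dosage counts the minor allele, this equals
#' mean(dosage)/2; columns that are entirely missing yield `NA`.
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector of allele frequencies (one per SNP).
#' @export
snp_maf <- function(g) {
  colMeans(g$dosage, na.rm = TRUE) / 2
}

#' Per-SNP fraction of missing genotypes
#' @param g A [genotype_matrix()].
#' @return Named numeric vector of missing proportions.
#' @export
snp_missing_fraction <- function(g) {
  colMeans(is.na(g$dosage))
}

#' Recode dosages so they count the minor allele
#'
#' Input dosages typically count the alternate allele, which is usually but
#' not always the minor allele. Any SNP whose alternate-allele frequency
#' (over non-missing genotypes) exceeds 0.5 is flipped (`x -> 2 - x`) so that
#' afterwards every column counts its minor allele. A frequency of exactly
#' 0.5 is left unflipped (deterministic tie rule). All-missing columns are
#' left untouched and flagged with a warning.
#'
#' @param g A [genotype_matrix()] with alternate-allele dosages.
#' @return A `genotype_matrix` with the `flipped` field recording which
#'   columns were swapped (an involution: recoding a flipped column again
#'   restores it).
#' @export
recode_minor <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  freq <- colMeans(g$dosage, na.rm = TRUE) / 2
  all_missing <- !is.finite(freq)
  if (any(all_missing)) {
    warning(sprintf("%d SNP(s) with all genotypes missing left unrecoded: %s",
                    sum(all_missing),
                    paste(utils::head(g$snp_ids[all_missing], 5), collapse = ", ")))
    freq[all_missing] <- 0
  }
  flip <- unname(freq > 0.5)
  if (any(flip)) {
    g$dosage[, flip] <- 2L - g$dosage[, flip, drop = FALSE]
  }
  g$flipped <- xor(g$flipped, flip)
  g
}

#' Apply the SNP inclusion filters
#'
#' Retains SNPs with missing fraction at most `max_missing_fraction` and
#' minor-allele frequency at least `maf_min` (both boundaries inclusive),
#' preserving the original SNP order. All removals are recorded in an
#' exclusion log. The operation is idempotent.
#'
#' @param g A recoded [genotype_matrix()] (see [recode_minor()]).
#' @param maf_min Minimum minor-allele frequency, default 0.001.
#' @param max_missing_fraction Maximum tolerated proportion of missing
#'   genotypes per SNP, default 0.25.
#' @return A list with `genotypes` (the filtered `genotype_matrix`) and
#'   `excluded`, a tibble with columns `snp_id` and `reason`
#'   (`"low_maf"`, `"missingness"`, or `"all_missing"`).
#' @export
filter_snps <- function(g, maf_min = 0.001, max_missing_fraction = 0.25) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  miss <- snp_missing_fraction(g)
  maf <- snp_maf(g)
  reason <- rep(NA_character_, length(maf))
  reason[miss >= 1] <- "all_missing"
  reason[is.na(reason) & miss > max_missing_fraction] <- "missingness"
  reason[is.na(reason) & maf < maf_min] <- "low_maf"
  keep <- is.na(reason)
  log <- tibble::tibble(snp_id = g$snp_ids[!keep], reason = reason[!keep])
  out <- genotype_matrix(g$dosage[, keep, drop = FALSE],
                         sample_ids = g$sample_ids,
                         snp_ids = g$snp_ids[keep],
                         positions = g$positions[keep],
                         flipped = g$flipped[keep])
  list(genotypes = out, excluded = log)
}

#' Read a genotype matrix from a TSV file
#'
#' Expected dialect: one header row of SNP identifiers, then one row per
#' sample whose first column is the sample identifier, remaining columns the
#' alternate-allele dosages (0/1/2, `NA` for missing).
#'
#' @param path Path to the TSV file.
#' @param positions Optional base-pair positions (defaults to column order).
#' @return A [genotype_matrix()] (not yet recoded; see [recode_minor()]).
#' @export
read_genotype_tsv <- function(path, positions = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = "NA", check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  genotype_matrix(m, sample_ids = ids, snp_ids = colnames(tab)[-1],
                  positions = positions %||% seq_len(ncol(m)))
}

#' Write a genotype matrix to TSV (same dialect as [read_genotype_tsv()])
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  tab <- data.frame(ID = g$sample_ids, g$dosage, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Converts the GT field of a biallelic VCF (v4.x) to alternate-allele
#' dosages; unphased and phased separators are both accepted and `./.`
#' becomes `NA`. Multi-allelic records are rejected.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return A [genotype_matrix()] of alternate-allele dosages with positions
#'   taken from the POS column; recode with [recode_minor()] before analysis.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(is.na(x) | x == "./." | x == ".", NA_integer_,
           vapply(strsplit(x, "/"), function(a) sum(a == "1"), integer(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  ids <- vcfR::getID(v)
  if (all(is.na(ids))) ids <- paste0("snp", seq_len(nrow(gt)))
  genotype_matrix(t(dos), sample_ids = colnames(gt), snp_ids = ids,
                  positions = as.integer(vcfR::getPOS(v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
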