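#' Default rare-haplotype-rich pool for a 5-SNP window
#'
#' Twelve haplotypes: two common ones carrying 86% of the mass and ten rare
#' ones (frequencies 0.004 to 0.02, several at or below 0.005), mimicking
#' the frequency spectrum seen in exome-derived 5-SNP blocks where rare
#' haplotypes dominate the list.
#'
#' @return Named numeric vector: names are 5-SNP binary haplotype strings,
#'   values their population frequencies (summing to 1).
#' @export
default_hap_pool <- function() {
  stats::setNames(
    c(0.46, 0.40, 0.02, 0.02, 0.02, 0.02, 0.02,
      0.0135, 0.0125, 0.005, 0.005, 0.004),
    c("00000", "01100", "10101", "01010", "00010", "00001",
      "10000", "01000", "00100", "11010", "00110", "11111"))
}

#' Configuration for the synthetic case-control cohort generator
#'
#' The generator draws diplotypes from a haplotype pool under the HWD
#' frequency model, assigns disease retrospectively through a logistic model
#' with planted per-haplotype log odds ratios (and optional binary-covariate
#' main and interaction effects), and fills fixed case/control quotas —
#' matching a case-control design with fixed margins. Genes longer than one
#' window are composed of independent 5-SNP segments, each drawn from the
#' pool; planted effects act on the haplotype of `risk_segment`.
#'
#' @param n_snps Number of SNPs in the gene (a multiple of the pool's
#'   window width); default 5.
#' @param hap_freq Named frequency vector over the haplotype pool (names are
#'   binary strings); default [default_hap_pool()].
#' @param d HWD parameter of the diplotype distribution; default 0 (HWE).
#' @param intercept Logistic intercept controlling baseline disease
#'   probability; default -1.5.
#' @param beta Named vector of per-haplotype log odds ratios (names must be
#'   pool haplotypes; unnamed haplotypes get 0). Default: all zero (null).
#' @param risk_segment Which 5-SNP segment the planted effects act on;
#'   default 1.
#' @param age_prob Prevalence of the binary covariate (e.g. age >= 55);
#'   default 0.35.
#' @param age_beta Covariate main-effect log odds ratio; default 0.
#' @param age_interaction Named vector of haplotype-by-covariate interaction
#'   log odds ratios; default none.
#' @param n_case,n_control Case and control quotas; defaults 456 and 1395,
#'   the 1:3 case-control ratio of a hypertension cohort of 1851 unrelated
#'   individuals.
#' @param missing_rate Per-SNP genotype missingness rate (scalar or length
#'   `n_snps`); default 0.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 5, hap_freq = default_hap_pool(), d = 0,
                       intercept = -1.5, beta = NULL, risk_segment = 1,
                       age_prob = 0.35, age_beta = 0, age_interaction = NULL,
                       n_case = 456, n_control = 1395, missing_rate = 0) {
  width <- nchar(names(hap_freq)[1])
  if (any(nchar(names(hap_freq)) != width))
    stop("all pool haplotypes must have the same length")
  if (n_snps %% width != 0)
    stop("n_snps must be a multiple of the pool haplotype length")
  if (abs(sum(hap_freq) - 1) > 1e-8) stop("hap_freq must sum to 1")
  if (anyDuplicated(names(hap_freq))) stop("duplicate pool haplotypes")
  if (d > 1 || d <= hwd_lower_bound(hap_freq)) stop("d outside admissible range")
  if (n_case <= 0 || n_control <= 0) stop("n_case and n_control must be > 0")
  b <- stats::setNames(rep(0, length(hap_freq)), names(hap_freq))
  if (!is.null(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% names(hap_freq)))
      stop("beta must be named by pool haplotypes")
    b[names(beta)] <- beta
  }
  gi <- stats::setNames(rep(0, length(hap_freq)), names(hap_freq))
  if (!is.null(age_interaction)) {
    if (is.null(names(age_interaction)) ||
        !all(names(age_interaction) %in% names(hap_freq)))
      stop("age_interaction must be named by pool haplotypes")
    gi[names(age_interaction)] <- age_interaction
  }
  n_seg <- n_snps %/% width
  if (risk_segment < 1 || risk_segment > n_seg) stop("invalid risk_segment")
  structure(list(n_snps = as.integer(n_snps), width = as.integer(width),
                 n_seg = as.integer(n_seg), hap_freq = hap_freq, d = d,
                 intercept = intercept, beta = b,
                 risk_segment = as.integer(risk_segment),
                 age_prob = age_prob, age_beta = age_beta,
                 age_interaction = gi,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 missing_rate = rep_len(missing_rate, n_snps)),
            class = "sim_config")
}

#' Simulate a case-control cohort with planted haplotype effects
#'
#' Repeatedly draws individuals — diplotype per segment from the HWD
#' diplotype distribution, binary covariate, disease status from the
#' logistic model — keeping them until the case and control quotas are
#' filled (retrospective sampling). Genotypes are allele-wise sums of the
#' two haplotypes with missingness injected per SNP; blood-pressure and
#' medication fields are synthesized so that [derive_status()] reproduces
#' the intended status exactly; ages are drawn consistently with the binary
#' age-group covariate.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param max_draws Attempt cap before giving up on unreachable quotas;
#'   default `500 * (n_case + n_control)`.
#' @return A list of class `sim_cohort`: `genotypes`
#'   ([genotype_matrix()]), `pheno` (tibble `ID,SBP,DBP,MED,AGE` plus
#'   derived `status`, `age_group`), `truth` (list: config, per-individual
#'   true diplotypes as string pairs, covariate, intended status).
#' @export
simulate_cohort <- function(cfg, seed = 1,
                            max_draws = 500 * (cfg$n_case + cfg$n_control)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  K <- length(cfg$hap_freq)
  f <- as.numeric(cfg$hap_freq)
  codes <- hap_code(names(cfg$hap_freq))
  pk <- rep(seq_len(K), times = K:1)
  pl <- unlist(lapply(seq_len(K), function(k) k:K))
  pp <- diplotype_probability(pk, pl, f, cfg$d)

  n_target <- cfg$n_case + cfg$n_control
  got_case <- 0L; got_ctrl <- 0L; drawn <- 0L
  h1 <- matrix(0L, n_target, cfg$n_seg)
  h2 <- matrix(0L, n_target, cfg$n_seg)
  ev <- integer(n_target); yv <- integer(n_target)
  filled <- 0L

  while ((got_case < cfg$n_case || got_ctrl < cfg$n_control) &&
         drawn < max_draws) {
    B <- min(5000L, max_draws - drawn)
    drawn <- drawn + B
    pair <- matrix(sample.int(length(pp), B * cfg$n_seg, replace = TRUE,
                              prob = pp), B, cfg$n_seg)
    a1 <- matrix(pk[pair], B, cfg$n_seg)
    a2 <- matrix(pl[pair], B, cfg$n_seg)
    e <- stats::rbinom(B, 1, cfg$age_prob)
    r1 <- a1[, cfg$risk_segment]; r2 <- a2[, cfg$risk_segment]
    lp <- cfg$intercept + cfg$beta[r1] + cfg$beta[r2] +
      e * (cfg$age_beta + cfg$age_interaction[r1] + cfg$age_interaction[r2])
    y <- stats::rbinom(B, 1, stats::plogis(lp))
    for (i in seq_len(B)) {
      want <- if (y[i] == 1L) got_case < cfg$n_case else got_ctrl < cfg$n_control
      if (!want) next
      filled <- filled + 1L
      h1[filled, ] <- a1[i, ]; h2[filled, ] <- a2[i, ]
      ev[filled] <- e[i]; yv[filled] <- y[i]
      if (y[i] == 1L) got_case <- got_case + 1L else got_ctrl <- got_ctrl + 1L
      if (got_case == cfg$n_case && got_ctrl == cfg$n_control) break
    }
  }
  if (got_case < cfg$n_case || got_ctrl < cfg$n_control)
    stop(sprintf(
      "could not fill quotas after %d draws (have %d cases, %d controls)",
      drawn, got_case, got_ctrl))

  # genotypes: allele-wise sums of the two haplotypes, segment by segment
  al <- hap_alleles(codes, cfg$width)
  dosage <- matrix(0L, n_target, cfg$n_snps)
  for (s in seq_len(cfg$n_seg)) {
    colsel <- ((s - 1L) * cfg$width + 1L):(s * cfg$width)
    dosage[, colsel] <- al[h1[, s], , drop = FALSE] +
      al[h2[, s], , drop = FALSE]
  }
  for (j in seq_len(cfg$n_snps)) {
    if (cfg$missing_rate[j] > 0) {
      miss <- stats::runif(n_target) < cfg$missing_rate[j]
      dosage[miss, j] <- NA_integer_
    }
  }
  ids <- sprintf("I%04d", seq_len(n_target))
  g <- genotype_matrix(dosage, sample_ids = ids,
                       snp_ids = sprintf("snp%02d", seq_len(cfg$n_snps)),
                       positions = seq_len(cfg$n_snps) * 1000L)

  # phenotype fields consistent with the intended status
  n <- n_target
  sbp <- dbp <- rep(NA_real_, n)
  med <- rep(NA_integer_, n)
  is_case <- yv == 1L
  med_case <- is_case & stats::runif(n) < 0.3
  sbp[is_case & !med_case] <- stats::runif(sum(is_case & !med_case), 141, 200)
  dbp[is_case & !med_case] <- stats::runif(sum(is_case & !med_case), 50, 90)
  med[is_case & !med_case] <- 0L
  sbp[med_case] <- stats::runif(sum(med_case), 90, 140)
  dbp[med_case] <- stats::runif(sum(med_case), 50, 90)
  med[med_case] <- 1L
  ctrl <- !is_case
  sbp[ctrl] <- stats::runif(sum(ctrl), 90, 140)
  dbp[ctrl] <- stats::runif(sum(ctrl), 50, 90)
  med[ctrl] <- ifelse(stats::runif(sum(ctrl)) < 0.8, 0L, NA_integer_)
  age <- ifelse(ev == 1L, stats::runif(n, 55, 85), stats::runif(n, 20, 54.9))
  pheno <- add_phenotype_status(tibble::tibble(
    ID = ids, SBP = round(sbp, 1), DBP = round(dbp, 1), MED = med,
    AGE = round(age, 1)))

  lab <- names(cfg$hap_freq)
  structure(
    list(genotypes = g, pheno = pheno,
         truth = list(config = cfg, seed = seed,
                      hap1 = matrix(lab[h1], n, cfg$n_seg),
                      hap2 = matrix(lab[h2], n, cfg$n_seg),
                      covariate = ev, status = ifelse(is_case, "CASE",
                                                      "CONTROL"))),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d individuals (%d cases), %d SNPs\n",
              nrow(x$genotypes$dosage), sum(x$truth$status == "CASE"),
              ncol(x$genotypes$dosage)))
  invisible(x)
}

#' Panel of independent null cohorts for calibration experiments
#'
#' @param cfg A [sim_config()]; its planted effects are forced to zero.
#' @param n_genes Number of independent cohorts.
#' @param seed Seed from which per-cohort seeds are drawn.
#' @return List of `n_genes` [simulate_cohort()] results.
#' @export
make_null_panel <- function(cfg, n_genes, seed = 1) {
  cfg$beta[] <- 0
  cfg$age_beta <- 0
  cfg$age_interaction[] <- 0
  set.seed(seed)
  seeds <- sample.int(2147483629, n_genes)
  lapply(seq_len(n_genes), function(i) simulate_cohort(cfg, seed = seeds[i]))
}
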