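test_that("simulated phenotypes round-trip through the case definition", {
  sim <- simulate_cohort(sim_config(n_case = 100, n_control = 300), seed = 3)
  expect_equal(sim$pheno$status, sim$truth$status)
  expect_equal(sum(sim$truth$status == "CASE"), 100L)
  expect_equal(sum(sim$truth$status == "CONTROL"), 300L)
  # genotypes are the allele-wise sums of the true diplotypes
  al1 <- do.call(rbind, lapply(sim$truth$hap1[, 1], function(s)
    as.integer(strsplit(s, "")[[1]])))
  al2 <- do.call(rbind, lapply(sim$truth$hap2[, 1], function(s)
    as.integer(strsplit(s, "")[[1]])))
  expect_equal(unname(sim$genotypes$dosage), al1 + al2)
  # age group consistent with synthesized ages
  expect_equal(sim$pheno$age_group, sim$truth$covariate)
})

test_that("null cohorts respect Hardy-Weinberg proportions per SNP", {
  set.seed(5)
  seeds <- sample.int(1e6, 100)
  pass <- 0; total <- 0
  for (s in seeds) {
    sim <- simulate_cohort(sim_config(n_case = 150, n_control = 450), seed = s)
    dos <- sim$genotypes$dosage
    for (j in seq_len(ncol(dos))) {
      x <- dos[, j]
      p <- mean(x) / 2
      if (p < 0.005) next  # too few copies for a meaningful test
      exp_p <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      obs <- tabulate(x + 1L, 3L)
      pv <- suppressWarnings(
        stats::chisq.test(obs, p = exp_p, simulate.p.value = TRUE,
                          B = 1000)$p.value)
      total <- total + 1
      pass <- pass + (pv > 0.01)
    }
  }
  expect_gte(pass / total, 0.95)
})

test_that("null cohorts show equal case and control haplotype frequencies", {
  sim <- simulate_cohort(sim_config(n_case = 500, n_control = 500), seed = 13)
  h_all <- c(sim$truth$hap1[, 1], sim$truth$hap2[, 1])
  y2 <- rep(truth_y(sim), 2)
  f_case <- mean(h_all[y2 == 1] == "01100")
  f_ctrl <- mean(h_all[y2 == 0] == "01100")
  se <- sqrt(0.4 * 0.6 * (1 / 1000 + 1 / 1000))
  expect_lt(abs(f_case - f_ctrl), 4 * se)
})

test_that("planted effects enrich the risk haplotype among cases as the model predicts", {
  hap <- "10101"
  or <- 3
  cfg <- sim_config(beta = stats::setNames(log(or), hap),
                    n_case = 456, n_control = 1395)
  # exact case/control haplotype frequencies under the logistic model
  K <- length(cfg$hap_freq)
  b <- cfg$beta
  exp_freq <- function(yv) {
    num <- 0; den <- 0
    for (k in 1:K) for (l in k:K) {
      pz <- diplotype_probability(k, l, as.numeric(cfg$hap_freq), cfg$d)
      p1 <- stats::plogis(cfg$intercept + b[k] + b[l])
      py <- if (yv == 1) p1 else 1 - p1
      cnt <- (names(cfg$hap_freq)[k] == hap) + (names(cfg$hap_freq)[l] == hap)
      num <- num + cnt * pz * py
      den <- den + 2 * pz * py
    }
    num / den
  }
  f_case_exp <- exp_freq(1)
  f_ctrl_exp <- exp_freq(0)
  expect_gt(f_case_exp, f_ctrl_exp)  # enrichment in expectation
  set.seed(6)
  obs_case <- obs_ctrl <- numeric(50)
  for (r in 1:50) {
    sim <- simulate_cohort(cfg, seed = 1000 + r)
    h_all <- c(sim$truth$hap1[, 1], sim$truth$hap2[, 1])
    y2 <- rep(truth_y(sim), 2)
    obs_case[r] <- mean(h_all[y2 == 1] == hap)
    obs_ctrl[r] <- mean(h_all[y2 == 0] == hap)
  }
  # observed enrichment matches the closed-form calculation within MC error
  se_case <- stats::sd(obs_case) / sqrt(50)
  se_ctrl <- stats::sd(obs_ctrl) / sqrt(50)
  expect_lt(abs(mean(obs_case) - f_case_exp), 4 * se_case)
  expect_lt(abs(mean(obs_ctrl) - f_ctrl_exp), 4 * se_ctrl)
  expect_gt(mean(obs_case), mean(obs_ctrl))
})

test_that("EM recovers pool frequencies from a large phase-rich cohort", {
  sim <- simulate_cohort(sim_config(n_case = 1250, n_control = 3750), seed = 29)
  hf <- em_frequencies(enumerate_diplotypes(sim$genotypes))
  pool <- sim$truth$config$hap_freq
  for (h in names(pool)) {
    est <- hf$freq[hf$label == h]
    if (length(est) == 0) est <- 0
    expect_lt(abs(est - pool[[h]]), 0.005)
  }
})

test_that("missingness is injected at the configured per-SNP rates", {
  cfg <- sim_config(missing_rate = c(0.25, 0, 0, 0, 0.05),
                    n_case = 400, n_control = 1200)
  sim <- simulate_cohort(cfg, seed = 37)
  n <- nrow(sim$genotypes$dosage)
  miss <- colMeans(is.na(sim$genotypes$dosage))
  expect_lt(abs(miss[1] - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_equal(unname(miss[2]), 0)
  expect_lt(abs(miss[5] - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("null panels use distinct seeds and zero out planted effects", {
  cfg <- sim_config(beta = c("10101" = log(3)), n_case = 30, n_control = 90)
  panel <- make_null_panel(cfg, 4, seed = 9)
  expect_length(panel, 4L)
  expect_true(all(vapply(panel, function(s)
    all(s$truth$config$beta == 0), logical(1))))
  expect_false(identical(panel[[1]]$genotypes$dosage,
                         panel[[2]]$genotypes$dosage))
})

test_that("unreachable quotas fail with a clear error", {
  cfg <- sim_config(intercept = -30, n_case = 50, n_control = 50)
  expect_error(simulate_cohort(cfg, seed = 1, max_draws = 20000),
               "could not fill quotas")
})

test_that("multi-segment genes tile independent windows", {
  cfg <- sim_config(n_snps = 15, n_case = 60, n_control = 180)
  sim <- simulate_cohort(cfg, seed = 41)
  expect_equal(ncol(sim$genotypes$dosage), 15L)
  expect_equal(ncol(sim$truth$hap1), 3L)
  # each segment's dosage reconstructs from that segment's haplotypes
  a1 <- do.call(rbind, lapply(sim$truth$hap1[, 2], function(s)
    as.integer(strsplit(s, "")[[1]])))
  a2 <- do.call(rbind, lapply(sim$truth$hap2[, 2], function(s)
    as.integer(strsplit(s, "")[[1]])))
  expect_equal(unname(sim$genotypes$dosage[, 6:10]), a1 + a2)
})
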