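# phase-unambiguous genotype data: only homozygotes and single-het individuals
phase_known_data <- function(n = 400, seed = 3) {
  set.seed(seed)
  f <- c(0.55, 0.3, 0.15)       # haplotypes 00, 01, 10
  codes <- c(0L, 1L, 2L)
  k1 <- sample(1:3, n, TRUE, f)
  k2 <- sample(1:3, n, TRUE, f)
  amb <- (pmin(k1, k2) == 2 & pmax(k1, k2) == 3)  # 01/10 double het
  k2[amb] <- k1[amb]                              # make phase unambiguous
  y <- stats::rbinom(n, 1, stats::plogis(-0.3 + 0.5 * ((k1 == 2) + (k2 == 2))))
  dos <- hap_alleles(codes, 2)[k1, ] + hap_alleles(codes, 2)[k2, ]
  list(dos = dos, y = y, k1 = k1, k2 = k2)
}

test_that("score test on phase-known data equals the empirical score statistic", {
  pd <- phase_known_data()
  exp <- enumerate_diplotypes(pd$dos)
  hf <- em_frequencies(exp)
  st <- score_test(exp, pd$y, hf)
  # expected counts are exact counts when phase is known
  e <- expected_hap_counts(exp, hf)
  for (h in seq_along(hf$label)) {
    idx <- match(hf$label[h], hap_string(c(0L, 1L, 2L), 2))
    true_cnt <- (pd$k1 == idx) + (pd$k2 == idx)
    expect_equal(unname(e[, h]), as.numeric(true_cnt), tolerance = 1e-8)
    # independent textbook computation of the empirical score z
    yc <- pd$y - mean(pd$y)
    U <- sum(yc * true_cnt)
    V <- sum(yc^2 * (true_cnt - mean(true_cnt))^2)
    expect_equal(unname(st$haplotypes$statistic[h]^2), U^2 / V,
                 tolerance = 1e-6)
  }
  # and agrees asymptotically with the GLM Rao score test
  x <- (pd$k1 == 2) + (pd$k2 == 2)
  rao <- stats::anova(stats::glm(pd$y ~ 1, family = stats::binomial()),
                      stats::glm(pd$y ~ x, family = stats::binomial()),
                      test = "Rao")$Rao[2]
  z2 <- st$haplotypes$statistic[st$haplotypes$hap == "01"]^2
  expect_equal(unname(z2 / rao), 1, tolerance = 0.1)
})

test_that("score test returns null results when expected counts carry no signal", {
  # every individual identical: no variation at all
  dos <- matrix(rep(c(1L, 0L), each = 40), 40, 2)
  exp <- enumerate_diplotypes(dos)
  expect_warning(st <- score_test(exp, rep(c(0L, 1L), 20)), "no variation")
  expect_true(all(st$haplotypes$p_value == 1))
  expect_equal(st$global$p_value, 1)
})

test_that("score global statistic is invariant to haplotype order", {
  pd <- phase_known_data(n = 200, seed = 9)
  exp <- enumerate_diplotypes(pd$dos)
  hf <- em_frequencies(exp)
  st1 <- score_test(exp, pd$y, hf)
  hf_rev <- hf
  rev_ord <- rev(seq_along(hf$freq))
  hf_rev$hap <- hf$hap[rev_ord]
  hf_rev$label <- hf$label[rev_ord]
  hf_rev$freq <- hf$freq[rev_ord]
  st2 <- score_test(exp, pd$y, hf_rev)
  expect_equal(st2$global$statistic, st1$global$statistic, tolerance = 1e-8)
  expect_equal(st2$global$df, st1$global$df)
})

test_that("EM-GLM on phase-known data reproduces ordinary logistic regression", {
  pd <- phase_known_data(n = 300, seed = 7)
  exp <- enumerate_diplotypes(pd$dos)
  fit <- glm_em_fit(exp, pd$y, tolerance = 0, profile = "hapassoc")
  expect_true(fit$converged)
  # design: counts of each non-baseline haplotype, baseline = most frequent
  x01 <- (pd$k1 == 2) + (pd$k2 == 2)
  x10 <- (pd$k1 == 3) + (pd$k2 == 3)
  ref <- stats::glm(pd$y ~ x01 + x10, family = stats::binomial())
  cf <- summary(ref)$coefficients
  h <- fit$haplotypes
  expect_equal(unname(h$estimate[h$hap == "01"]), unname(cf["x01", 1]),
               tolerance = 1e-5)
  expect_equal(unname(h$estimate[h$hap == "10"]), unname(cf["x10", 1]),
               tolerance = 1e-5)
  # with phase known the joint information is block diagonal, so the
  # regression-block SEs equal the GLM SEs
  expect_equal(unname(h$se[h$hap == "01"]), unname(cf["x01", 2]),
               tolerance = 1e-3)
  expect_equal(unname(h$se[h$hap == "10"]), unname(cf["x10", 2]),
               tolerance = 1e-3)
})

test_that("pooling merges sub-tolerance haplotypes and is floored for profile glm", {
  set.seed(15)
  sim <- simulate_cohort(sim_config(n_case = 150, n_control = 450), seed = 20)
  exp <- enumerate_diplotypes(sim$genotypes)
  y <- truth_y(sim)[exp$kept]
  fit <- glm_em_fit(exp, y, tolerance = 0.05, profile = "glm")
  h <- fit$haplotypes
  expect_true("POOLED" %in% h$hap)
  rare <- fit$hf$freq[-1][fit$hf$freq[-1] < 0.05]
  expect_equal(h$freq[h$hap == "POOLED"], sum(rare), tolerance = 1e-9)
  expect_false(any(h$hap[h$freq < 0.05 & h$hap != "POOLED"] != "POOLED"))
  # POOLED is never a significant haplotype
  expect_false(isTRUE(h$significant[h$hap == "POOLED"]))
  # profile glm floors the tolerance at 0.001
  fit2 <- glm_em_fit(exp, y, tolerance = 0, profile = "glm")
  expect_equal(fit2$tolerance, 0.001)
})

test_that("non-convergence from separation is detected and carries no p-values", {
  # a rare haplotype carried only by cases: the coefficient diverges
  set.seed(2)
  n <- 60
  k1 <- rep(1L, n); k2 <- rep(1L, n)
  y <- rep(c(0L, 1L), each = n / 2)
  k2[y == 1][1:3] <- 2L   # hap 01 only among cases
  k2[y == 0][1:4] <- 3L   # hap 10 only among controls, for contrast
  dos <- hap_alleles(c(0L, 1L, 2L), 2)[k1, ] + hap_alleles(c(0L, 1L, 2L), 2)[k2, ]
  fit <- glm_em_fit(enumerate_diplotypes(dos), y, tolerance = 0,
                    profile = "hapassoc")
  expect_false(fit$converged)
  expect_true(all(is.na(fit$haplotypes$p_value)))
  expect_true(all(is.na(fit$haplotypes$significant)))
})

test_that("EM-GLM and score test agree on the direction of common-haplotype effects", {
  # both non-baseline haplotypes carry clear risk effects of the same sign;
  # (marginal score and multivariate Wald directions can legitimately differ
  # for weak effects because haplotype counts are compositionally correlated)
  set.seed(11)
  n <- 500
  f <- c(0.55, 0.3, 0.15)
  k1 <- sample(1:3, n, TRUE, f); k2 <- sample(1:3, n, TRUE, f)
  amb <- (pmin(k1, k2) == 2 & pmax(k1, k2) == 3)
  k2[amb] <- k1[amb]
  b <- c(0, 0.6, 0.6)
  y <- stats::rbinom(n, 1, stats::plogis(-0.6 + b[k1] + b[k2]))
  dos <- hap_alleles(c(0L, 1L, 2L), 2)[k1, ] + hap_alleles(c(0L, 1L, 2L), 2)[k2, ]
  exp <- enumerate_diplotypes(dos)
  hf <- em_frequencies(exp)
  st <- score_test(exp, y, hf)
  gf <- glm_em_fit(exp, y, tolerance = 0)
  expect_true(gf$converged)
  for (h in gf$haplotypes$hap) {
    zs <- st$haplotypes$statistic[st$haplotypes$hap == h]
    zb <- gf$haplotypes$statistic[gf$haplotypes$hap == h]
    if (abs(zs) > 1 || abs(zb) > 1)
      expect_equal(unname(sign(zb)), unname(sign(zs)))
  }
})

test_that("single-SNP scan handles monomorphic SNPs and detects planted effects", {
  set.seed(33)
  n <- 800
  x <- stats::rbinom(n, 2, 0.2)
  y <- stats::rbinom(n, 1, stats::plogis(-1 + log(2) * x))
  dos <- cbind(mono = rep(0L, n), assoc = as.integer(x),
               nullsnp = stats::rbinom(n, 2L, 0.3))
  g <- genotype_matrix(dos, positions = c(100L, 200L, 300L))
  res <- single_snp_scan(g, y)
  expect_true(is.na(res$p_value[res$snp_id == "mono"]))
  expect_false(res$significant[res$snp_id == "mono"])
  expect_lt(res$p_value[res$snp_id == "assoc"], 0.05)
  ref <- summary(stats::glm(y ~ x, family = stats::binomial()))$coefficients
  expect_equal(res$p_value[res$snp_id == "assoc"], unname(ref[2, 4]),
               tolerance = 1e-9)
})

test_that("single-SNP Wald test is calibrated under the null", {
  set.seed(44)
  hits <- 0
  B <- 400
  for (b in seq_len(B)) {
    x <- stats::rbinom(300, 2, 0.25)
    y <- stats::rbinom(300, 1, 0.3)
    g <- genotype_matrix(matrix(as.integer(x), ncol = 1), positions = 1L)
    hits <- hits + sum(single_snp_scan(g, y)$significant, na.rm = TRUE)
  }
  # binomial 99% band around 0.05
  expect_gt(hits / B, 0.05 - 2.58 * sqrt(0.05 * 0.95 / B))
  expect_lt(hits / B, 0.05 + 2.58 * sqrt(0.05 * 0.95 / B))
})
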