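test_that("closed-form marginal prior tail matches Monte-Carlo marginalization", {
  for (par in list(c(log(1.1), 20, 20), c(0.3, 5, 8), c(0.05, 1, 20))) {
    closed <- lbl_prior_tail(par[1], par[2], par[3])
    mc <- mc_prior_tail(par[1], par[2], par[3], n = 1e6, seed = 42)
    expect_equal(closed, mc, tolerance = 0.003)
  }
})

test_that("Bayes factor behaves correctly at its reference points", {
  eps <- log(1.1)
  # posterior identical in law to the prior: BF = 1 within MC tolerance
  set.seed(8)
  lam <- stats::rgamma(2e5, 20, rate = 20)
  b <- stats::rexp(2e5, rate = lam) * sample(c(-1, 1), 2e5, replace = TRUE)
  bf <- bayes_factor(b, epsilon = eps)
  expect_equal(bf$bf, 1, tolerance = 0.05)
  # all posterior mass outside the null interval: reported above the cap
  bf2 <- bayes_factor(rep(c(0.5, -0.7), 600), epsilon = eps)
  expect_true(bf2$capped)
  expect_equal(bf2$label, ">100")
  # all posterior mass inside: BF below 0.01
  bf3 <- bayes_factor(stats::runif(2000, -0.01, 0.01), epsilon = eps)
  expect_lt(bf3$bf, 0.01)
  expect_error(bayes_factor(rep(0.2, 2000), epsilon = -1), "positive")
  expect_error(bayes_factor(rep(0.2, 10)), "1000")
})

test_that("retrospective diplotype probabilities normalize for each disease status", {
  f <- c(0.55, 0.25, 0.15, 0.05)
  d <- 0.1
  a <- -0.8
  beta <- c(0.9, -0.4, 1.4)  # per non-baseline haplotype
  bfull <- c(0, beta)
  for (yv in 0:1) {
    th <- 0
    for (k in 1:4) for (l in k:4) {
      p1 <- stats::plogis(a + bfull[k] + bfull[l])
      th <- th + diplotype_probability(k, l, f, d) * (if (yv == 1) p1 else 1 - p1)
    }
    tot <- 0
    for (k in 1:4) for (l in k:4) {
      p1 <- stats::plogis(a + bfull[k] + bfull[l])
      tot <- tot + diplotype_probability(k, l, f, d) *
        (if (yv == 1) p1 else 1 - p1) / th
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

# shared 3-haplotype phase-known toy
make_toy <- function(n = 300, seed = 99) {
  set.seed(seed)
  f_true <- c(0.5, 0.3, 0.2)
  codes <- c(0L, 1L, 2L)
  k1 <- sample(1:3, n, TRUE, f_true)
  k2 <- sample(1:3, n, TRUE, f_true)
  b_true <- c(0, 0.8, -0.5)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + b_true[k1] + b_true[k2]))
  exp <- enumerate_diplotypes(hap_alleles(codes, 2)[k1, ] +
                                hap_alleles(codes, 2)[k2, ])
  list(exp = exp, y = y[exp$kept], k1 = k1, k2 = k2, codes = codes)
}

test_that("LBL chains are bit-identical given the same seed", {
  toy <- make_toy(150)
  ctrl <- lbl_control(n_iter = 2000, burn_in = 500)
  f1 <- lbl_fit(toy$exp, toy$y, control = ctrl, seed = 17)
  f2 <- lbl_fit(toy$exp, toy$y, control = ctrl, seed = 17)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$samples, f2$samples)
  f3 <- lbl_fit(toy$exp, toy$y, control = ctrl, seed = 18)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("degenerate LBL inputs are rejected", {
  # single-haplotype window: no contrast
  dos <- matrix(0L, 30, 3)
  e <- enumerate_diplotypes(dos)
  expect_error(lbl_fit(e, rep(c(0L, 1L), 15)), "no contrast")
  # all-case input
  toy <- make_toy(60)
  expect_error(lbl_fit(toy$exp, rep(1L, length(toy$y))), "cases and controls")
  expect_error(lbl_fit(toy$exp, toy$y[-1]), "align")
})

test_that("posterior mean tracks the penalized retrospective maximizer", {
  toy <- make_toy(300, seed = 5)
  hf <- em_frequencies(toy$exp)
  ctrl <- lbl_control(n_iter = 6000, burn_in = 2000,
                      a_lambda = 1, b_lambda = 20)
  fit <- lbl_fit(toy$exp, toy$y, start = hf, control = ctrl, seed = 2)
  ok1 <- match(hap_string(toy$codes[toy$k1], 2), hf$label)
  ok2 <- match(hap_string(toy$codes[toy$k2], 2), hf$label)
  K <- length(hf$freq)
  negpen <- function(th) {
    f <- exp(c(0, th[(K + 1):(2 * K - 1)])); f <- f / sum(f)
    dmin <- -min(f) / (1 - min(f))
    -(retro_loglik(th[1], th[2:K], f, dmin + (1 - dmin) * stats::plogis(th[2 * K]),
                   ok1, ok2, toy$y) +
        stats::dnorm(th[1], 0, ctrl$a_prior_sd, log = TRUE))
  }
  o <- stats::optim(c(0, rep(0, K - 1), log(hf$freq[-1] / hf$freq[1]), 0),
                    negpen, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
  expect_equal(unname(colMeans(fit$samples)), unname(o$par[2:K]),
               tolerance = 0.12)
})

test_that("stronger shrinkage priors pull null coefficients toward zero", {
  set.seed(12)
  toy <- make_toy(250, seed = 31)
  y0 <- permute_phenotypes(toy$y, seed = 4)  # break any association
  weak <- lbl_fit(toy$exp, y0, seed = 5,
                  control = lbl_control(n_iter = 4000, burn_in = 1000,
                                        a_lambda = 5, b_lambda = 20))
  strong <- lbl_fit(toy$exp, y0, seed = 5,
                    control = lbl_control(n_iter = 4000, burn_in = 1000,
                                          a_lambda = 100, b_lambda = 20))
  expect_lt(stats::median(abs(strong$summary$beta_mean)),
            stats::median(abs(weak$summary$beta_mean)))
})

test_that("constant covariate collapses the interaction model to main effects", {
  toy <- make_toy(120, seed = 13)
  ctrl <- lbl_control(n_iter = 2000, burn_in = 500)
  base <- lbl_fit(toy$exp, toy$y, control = ctrl, seed = 9)
  expect_warning(
    gx <- lbl_fit_gxe(toy$exp, toy$y, covariate = rep(0L, length(toy$y)),
                      control = ctrl, seed = 9),
    "constant covariate")
  expect_identical(gx$summary, base$summary)
})

test_that("interaction model labels covariate and product terms", {
  toy <- make_toy(200, seed = 23)
  set.seed(41)
  cov <- stats::rbinom(length(toy$y), 1, 0.4)
  fit <- lbl_fit_gxe(toy$exp, toy$y, covariate = cov, seed = 3,
                     control = lbl_control(n_iter = 3000, burn_in = 1000))
  expect_true("covariate" %in% fit$summary$term)
  expect_true(any(grepl(":covariate$", fit$summary$term)))
  K <- length(fit$hf$freq)
  expect_equal(nrow(fit$summary), 2 * K - 1)
  expect_true(all(fit$summary$OR > 0))
  # credible intervals contain the posterior mean
  expect_true(all(fit$summary$ci_low <= fit$summary$beta_mean &
                    fit$summary$beta_mean <= fit$summary$ci_high))
})
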