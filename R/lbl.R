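#' Control parameters for the logistic Bayesian LASSO sampler
#'
#' @param n_iter Total MCMC iterations (default 50000).
#' @param burn_in Burn-in iterations discarded from summaries (default 20000).
#' @param epsilon Half-width of the null interval on `|beta|` used by the
#'   Bayes factor; default `log(1.1)`, i.e. "null" means an odds ratio
#'   within (1/1.1, 1.1). Set `epsilon_scale = "or"` to interpret `epsilon`
#'   as an odds-ratio bound instead (`|beta| <= log(epsilon)`).
#' @param epsilon_scale `"beta"` (default) or `"or"`.
#' @param a_lambda,b_lambda Shape and rate of the Gamma hyper prior on the
#'   double-exponential rate `lambda` (defaults 20, 20, prior mean 1).
#' @param bf_threshold Bayes factor declaring significance (default 2).
#' @param bf_cap Bayes factors above this are reported as `">cap"`
#'   (default 100).
#' @param sd_beta,sd_a Initial random-walk proposal standard deviations for
#'   the coefficients and intercept.
#' @param dirichlet_c Initial concentration of the Dirichlet proposal for
#'   the frequency vector (proposal `Dirichlet(c * f)`).
#' @param sd_pe Initial logit-scale proposal sd for the covariate frequency
#'   (interaction models only).
#' @param a_prior_sd Standard deviation of the normal prior on the
#'   intercept (default 2). The retrospective likelihood identifies the
#'   intercept only weakly — it has a near-flat ridge along which the
#'   intercept, haplotype frequencies and HWD parameter trade off — so a
#'   proper, moderately diffuse prior is required; N(0, 2) covers baseline
#'   disease odds from roughly 1:50 to 50:1 within two standard deviations.
#' @param adapt Adapt proposal scales during burn-in (frozen afterwards);
#'   default `TRUE`. Adaptation is deterministic given the seed.
#' @return A list of class `lbl_control`.
#' @export
lbl_control <- function(n_iter = 50000, burn_in = 20000,
                        epsilon = log(1.1), epsilon_scale = c("beta", "or"),
                        a_lambda = 20, b_lambda = 20,
                        bf_threshold = 2, bf_cap = 100,
                        sd_beta = 0.3, sd_a = 0.2, dirichlet_c = 2000,
                        sd_pe = 0.3, a_prior_sd = 2, adapt = TRUE) {
  epsilon_scale <- match.arg(epsilon_scale)
  eps <- if (epsilon_scale == "or") log(epsilon) else epsilon
  if (eps <= 0) stop("epsilon must be positive (odds-ratio bound > 1)")
  if (n_iter <= burn_in || burn_in < 0) stop("need n_iter > burn_in >= 0")
  if (bf_threshold <= 0) stop("bf_threshold must be positive")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 epsilon = eps, a_lambda = a_lambda, b_lambda = b_lambda,
                 bf_threshold = bf_threshold, bf_cap = bf_cap,
                 sd_beta = sd_beta, sd_a = sd_a, dirichlet_c = dirichlet_c,
                 sd_pe = sd_pe, a_prior_sd = a_prior_sd, adapt = adapt),
            class = "lbl_control")
}

#' Prior probability that a coefficient exceeds the null interval
#'
#' Under the Bayesian-LASSO prior, `beta ~ DoubleExponential(0, lambda)`
#' with `lambda ~ Gamma(a, b)`, the marginal tail probability
#' `Pr(|beta| > eps) = E[exp(-lambda * eps)] = (b / (b + eps))^a`
#' (the Gamma moment generating function at `-eps`).
#'
#' @param epsilon Null half-width on `|beta|` (> 0).
#' @param a_lambda,b_lambda Gamma hyper-prior shape and rate.
#' @return `Pr(|beta| > epsilon)` under the marginal prior.
#' @export
lbl_prior_tail <- function(epsilon, a_lambda = 20, b_lambda = 20) {
  if (epsilon <= 0) stop("epsilon must be positive")
  (b_lambda / (b_lambda + epsilon))^a_lambda
}

#' Bayes factor for a haplotype (or covariate) effect
#'
#' `BF = [Pr_post(|beta| > eps) / Pr_post(|beta| <= eps)] /
#'       [Pr_prior(|beta| > eps) / Pr_prior(|beta| <= eps)]`,
#' the ratio of posterior to prior odds of the coefficient lying outside the
#' null interval. When no posterior mass is inside the interval the BF is
#' unbounded and is reported as exceeding the cap.
#'
#' @param beta_samples Numeric vector of post-burn-in posterior draws
#'   (at least 1000).
#' @param epsilon Null half-width on `|beta|`.
#' @param a_lambda,b_lambda Hyper-prior parameters (see [lbl_prior_tail()]).
#' @param cap Reporting cap; default 100.
#' @return A list with `bf` (numeric, `Inf` when unbounded), `capped`
#'   (logical, `TRUE` when `bf > cap`), and `label` (e.g. `">100"`).
#' @export
bayes_factor <- function(beta_samples, epsilon = log(1.1),
                         a_lambda = 20, b_lambda = 20, cap = 100) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (length(beta_samples) < 1000)
    stop("need at least 1000 posterior samples for a stable Bayes factor")
  p_out <- mean(abs(beta_samples) > epsilon)
  prior_out <- lbl_prior_tail(epsilon, a_lambda, b_lambda)
  prior_odds <- prior_out / (1 - prior_out)
  if (p_out == 1) {
    bf <- Inf
  } else {
    bf <- (p_out / (1 - p_out)) / prior_odds
  }
  capped <- bf > cap
  list(bf = bf, capped = capped,
       label = if (capped) paste0(">", format(cap)) else
         formatC(bf, digits = 3, format = "fg"))
}

#' Fit the retrospective-likelihood logistic Bayesian LASSO for one window
#'
#' Models the probability of each individual's latent diplotype given disease
#' status. Disease odds follow a logistic model in the copy counts of each
#' non-baseline haplotype (baseline = most frequent); coefficients get
#' double-exponential shrinkage priors with a Gamma hyper prior on the rate,
#' haplotype frequencies get a flat Dirichlet prior, and excess homozygosity
#' is captured by an HWD parameter uniform on its admissible range.
#' Inference is Metropolis-within-Gibbs MCMC over the coefficients,
#' intercept, shrinkage rate (conjugate Gamma update), frequencies
#' (Dirichlet proposal), HWD parameter, and latent diplotypes. Association
#' is tested per haplotype by the Bayes factor of [bayes_factor()].
#'
#' @param exp A [enumerate_diplotypes()] expansion for the window (dropped
#'   individuals are excluded).
#' @param y Binary case-control labels (1 = case) aligned with the *kept*
#'   individuals of `exp`.
#' @param start Optional [em_frequencies()] fit giving starting frequencies;
#'   computed from `exp` when `NULL`.
#' @param control A [lbl_control()] list.
#' @param covariate Optional binary covariate over kept individuals; when
#'   supplied, covariate main and haplotype-by-covariate interaction effects
#'   are added under haplotype-environment independence.
#' @param seed Integer seed making the chain reproducible; default 1.
#' @return An object of class `lbl_fit`: list with `summary` (tibble with
#'   one row per tested effect: `term`, `hap`, `freq`, `beta_mean`,
#'   `ci_low`, `ci_high`, `OR`, `bf`, `bf_label`, `significant`), `hf`
#'   (starting frequencies), `f_post` (posterior mean frequencies),
#'   `samples` (post-burn-in coefficient draws), `a`, `lambda`, `d` draws,
#'   acceptance rates, `control`, `seed`, `n_used`.
#' @export
lbl_fit <- function(exp, y, start = NULL, control = lbl_control(),
                    covariate = NULL, seed = 1) {
  stopifnot(inherits(exp, "diplotype_expansion"))
  n <- length(exp$pairs)
  if (length(y) != n)
    stop("y must align with the kept individuals of the expansion")
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("labels must be binary 0/1")
  if (all(y == 1L) || all(y == 0L))
    stop("need both cases and controls")
  gxe <- !is.null(covariate)
  if (gxe) {
    covariate <- as.integer(covariate)
    if (length(covariate) != n || anyNA(covariate) ||
        !all(covariate %in% 0:1))
      stop("covariate must be binary with no missing values")
    if (length(unique(covariate)) == 1L) {
      warning("constant covariate: interaction terms dropped, fitting main-effects model")
      return(lbl_fit(exp, y, start = start, control = control, seed = seed))
    }
  }
  if (is.null(start)) start <- em_frequencies(exp)
  idx <- index_expansion(exp, start)
  K <- length(start$freq)
  if (K < 2L) stop("no contrast: only one haplotype in the window")

  np <- tabulate(idx$i, n)
  offsets <- c(0L, cumsum(np))

  set.seed(seed)
  res <- lbl_mcmc_cpp(y, idx$k1 - 1L, idx$k2 - 1L, offsets, K, start$freq,
                      if (gxe) covariate else integer(0), gxe,
                      control$n_iter, control$burn_in,
                      control$a_lambda, control$b_lambda,
                      control$sd_beta, control$sd_a, control$dirichlet_c,
                      control$sd_pe, control$a_prior_sd, control$adapt)

  terms <- paste0("hap_", start$label[-1])
  haps <- start$label[-1]
  freqs <- start$freq[-1]
  if (gxe) {
    terms <- c(terms, "covariate", paste0("hap_", start$label[-1], ":covariate"))
    haps <- c(haps, NA_character_, start$label[-1])
    freqs <- c(freqs, NA_real_, start$freq[-1])
  }
  bm <- colMeans(res$beta)
  ci <- apply(res$beta, 2, stats::quantile, probs = c(0.025, 0.975))
  bfs <- lapply(seq_along(terms), function(j)
    bayes_factor(res$beta[, j], epsilon = control$epsilon,
                 a_lambda = control$a_lambda, b_lambda = control$b_lambda,
                 cap = control$bf_cap))
  summary <- tibble::tibble(
    term = terms, hap = haps, freq = freqs,
    beta_mean = bm, ci_low = ci[1, ], ci_high = ci[2, ],
    OR = exp(bm),
    bf = vapply(bfs, function(b) b$bf, numeric(1)),
    bf_label = vapply(bfs, function(b) b$label, character(1)),
    significant = vapply(bfs, function(b)
      b$capped || b$bf > control$bf_threshold, logical(1)))

  structure(
    list(summary = summary, hf = start,
         f_post = stats::setNames(as.numeric(res$f_mean), start$label),
         baseline = start$label[1],
         samples = res$beta, a = res$a, lambda = res$lambda, d = res$d,
         accept = list(beta = res$accept_beta, a = res$accept_a,
                       f = res$accept_f, d = res$accept_d,
                       pE = res$accept_pE),
         gxe = gxe, control = control, seed = seed, n_used = n),
    class = "lbl_fit"
  )
}

#' Logistic Bayesian LASSO with a binary covariate and haplotype
#' interactions
#'
#' Convenience wrapper around [lbl_fit()] that always includes the covariate
#' main effect and haplotype-by-covariate interactions (e.g. age dichotomized
#' at 55), under the model's haplotype-environment independence assumption.
#'
#' @inheritParams lbl_fit
#' @param covariate Binary covariate (required here).
#' @return An `lbl_fit` object whose summary includes `covariate` and
#'   `hap:covariate` rows.
#' @export
lbl_fit_gxe <- function(exp, y, covariate, start = NULL,
                        control = lbl_control(), seed = 1) {
  if (is.null(covariate)) stop("covariate is required")
  lbl_fit(exp, y, start = start, control = control,
          covariate = covariate, seed = seed)
}

#' @export
print.lbl_fit <- function(x, ...) {
  cat(sprintf("lbl_fit: %d individuals, baseline haplotype %s%s\n",
              x$n_used, x$baseline,
              if (x$gxe) ", with covariate interactions" else ""))
  print(x$summary)
  invisible(x)
}
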