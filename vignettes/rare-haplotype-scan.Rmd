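---
title: "Gene-wide rare-haplotype association scans with rhapscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-wide rare-haplotype association scans with rhapscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhapscan)
```

## The problem

Exome and sequencing panels are dominated by rare variants, and haplotypes
built from rare SNPs are rarer still. Standard frequentist haplotype tests
(score tests, EM-GLM Wald tests) either pool rare haplotypes into an
uninformative "POOLED" category, fail to converge, or — when rare
haplotypes are modeled individually — produce inflated false-positive
rates, because their asymptotic approximations break down for haplotypes
carried by a handful of individuals. `rhapscan` implements a
case-control analysis designed for this regime: a gene is scanned with
sliding, overlapping windows of consecutive SNPs (default width 5, step 1,
so `n - 4` windows for `n` SNPs), and within each window individual
haplotypes — including rare ones — are tested with a retrospective-likelihood
logistic Bayesian LASSO (LBL), alongside the standard frequentist
comparators and a single-SNP logistic scan. A permutation module estimates
per-method false-positive proportions by destroying the
genotype-phenotype link and re-running the scan.

## Cohort ingestion and the case definition

Genotypes enter as alternate-allele dosages (VCF GT fields or a TSV
matrix). Because the alternate allele is not always the minor allele,
`recode_minor()` flips any SNP whose alternate-allele frequency exceeds
0.5 (computed over non-missing genotypes; a tie at exactly 0.5 is left
unflipped so the operation is deterministic). `filter_snps()` then keeps
SNPs with MAF at least 0.001 and at most 25% missing genotypes, both
boundaries inclusive.

The binary hypertension status is a disjunction: a person is a case if
SBP > 140 mmHg, or DBP > 90 mmHg, or they take antihypertensive
medication; one satisfied trigger suffices even if other fields are
missing. A person whose observed pressures are all at or below threshold
and whose medication field is "no" or missing is a control, provided at
least one pressure was observed. Everyone else is excluded. The
dichotomized age covariate is the indicator `age >= 55` (the cut could
equally be defined as `> 55`; we fixed the closed-below convention once
and document it here).

## Window haplotype reconstruction

Within a window, each individual's unphased dosages are expanded into the
set of compatible unordered haplotype pairs (`2^(h-1)` pairs for `h`
heterozygous SNPs). Individuals with two or more missing genotypes in the
window are dropped — window-locally, so an individual may be excluded from
one window and analyzed in the next; individuals with exactly one missing
genotype are expanded over the three possible dosages at that SNP. The
three completions are enumerated without prior weighting: their relative
plausibility is resolved by the EM weights, not by a hard-coded prior.

`em_frequencies()` estimates haplotype frequencies by standard EM under
Hardy-Weinberg equilibrium, starting from equal weights over each
individual's compatible pairs, stopping when the log-likelihood gain falls
below 1e-8 (cap 1000 iterations). Phase ambiguity makes many haplotypes
"compatible" that are actually absent; EM drives their frequencies to
numerical zero, and haplotypes below 1e-8 are pruned from the list, which
keeps downstream models on the haplotypes actually supported by the data.
The estimated list, ordered by decreasing frequency (ties broken by the
binary haplotype string), seeds every downstream method; the most frequent
haplotype is the regression baseline throughout.

## The logistic Bayesian LASSO

LBL models the probability of haplotypes *given* disease status — a
retrospective likelihood matching case-control ascertainment. For
individual $i$ with latent diplotype $Z_i$,

$$P(Z_i = z \mid Y_i = y) =
  \frac{P(y \mid z)\, P(z \mid f, d)}{\sum_{z'} P(y \mid z')\, P(z' \mid f, d)},$$

where the diplotype distribution allows Hardy-Weinberg disequilibrium:
$P\{(k,l)\} = 2(1-d) f_k f_l$ for $k \ne l$ and $d f_k + (1-d) f_k^2$ on
the diagonal, with $d \in (d_{\min}, 1]$, $d_{\min} = -\min_k f_k/(1-f_k)$
so that all probabilities stay non-negative. Disease odds follow a
logistic model in the copy counts $x(z)$ of each non-baseline haplotype:
$P(y{=}1 \mid z) = \mathrm{logit}^{-1}(a + x(z)^\top \beta)$.

Priors implement the Bayesian LASSO: each $\beta_j$ has a
double-exponential prior with density $(\lambda/2) e^{-\lambda |\beta_j|}$,
and $\lambda$ carries a Gamma($a_\lambda$, $b_\lambda$) hyper prior
(default 20, 20: prior mean 1, tight enough to shrink noise on rare
haplotypes while letting real effects through). Frequencies get a flat
Dirichlet prior and $d$ a uniform prior on its admissible range.
Inference is Metropolis-within-Gibbs (C++ core): random-walk updates for
$a$ and each $\beta_j$, a conjugate Gamma update for $\lambda$ given
$\sum_j |\beta_j|$, a Dirichlet proposal centered at the current $f$
(concentration adapted during burn-in), an independent uniform proposal
for $d$ within the admissible range recomputed after every $f$ move, and
exact discrete conditionals for each $Z_i$ over its compatible pairs.
Proposal scales adapt toward standard acceptance targets during burn-in
only and are frozen afterwards, so chains are exactly reproducible from
the seed. Defaults are 50000 iterations with 20000 burn-in; the test
suite and the bundled experiments use 10000/3000, which on windows of
10-15 haplotypes mixes well enough for Bayes-factor decisions.

### Identifiability of the intercept

The retrospective likelihood identifies the intercept only weakly: there
is a near-flat ridge along which $a$, $f$, $d$ and $\beta$ co-drift while
the fitted case and control diplotype distributions barely change — indeed
the unpenalized likelihood can be marginally *higher* far out on the
ridge, and when $\beta \approx 0$ the likelihood contains no information
about $a$ at all. With a very diffuse intercept prior the chain wanders
onto this ridge and haplotype effects become prior-dependent. The
intercept prior is therefore a proper normal with standard deviation 2
(covering baseline disease odds from roughly 1:50 to 50:1 within two
standard deviations — ample for any realistic case-control study), which
cuts the ridge and makes the posterior concentrate where the model is
identified. We validated the sampler on a phase-known three-haplotype toy
against the penalized retrospective-likelihood maximizer and an
importance-sampling gold standard.

### Bayes factors

Association is tested per effect by the Bayes factor of
$H_1: |\beta| > \varepsilon$ against $H_0: |\beta| \le \varepsilon$,
the ratio of posterior to prior odds. The default null half-width is
$\varepsilon = \log 1.1$ ("null" = odds ratio within 1/1.1 to 1.1); it can
be given on the odds-ratio scale instead, which is monotone-equivalent.
The marginal prior tail has closed form
$\Pr(|\beta| > \varepsilon) = (b_\lambda/(b_\lambda+\varepsilon))^{a_\lambda}$
(the Gamma moment generating function evaluated at $-\varepsilon$); the
test suite cross-checks it by Monte-Carlo marginalization. A BF above 2
declares significance; when no posterior draw falls inside the null
interval the BF is unbounded and is reported as ">100" (the cap is
configurable), matching how overwhelming evidence is conventionally
displayed.

The interaction model adds a binary covariate (e.g. age ≥ 55) and
haplotype-by-covariate products, under haplotype-environment
independence: $P(Z, E) = P(Z \mid f, d) P(E)$ with a Bernoulli frequency
parameter for the covariate (logit random-walk update, flat prior). A
constant covariate degenerates to the main-effects model (with a
warning), which keeps scans on homogeneous strata well-defined.

## Frequentist comparators

- `score_test()` estimates frequencies by EM independently of the trait,
  forms per-individual expected haplotype copy counts $e_{ih}$, and tests
  $U_h = \sum_i (y_i - \bar y) e_{ih}$ against the empirical variance
  $V = \sum_i (y_i - \bar y)^2 (e_i - \bar e)(e_i - \bar e)^\top$;
  the global statistic is $U^\top V^- U$ with a generalized inverse on
  $\mathrm{rank}(V)$ degrees of freedom. We use the empirical score
  covariance rather than an EM-information-corrected variance: the two are
  asymptotically equivalent under the null and the empirical form is far
  simpler; this is a documented divergence from the classical
  implementation.
- `glm_em_fit()` is the prospective EM-GLM: pseudo-individuals (one per
  compatible pair) weighted by $P(y \mid \text{pair}, \beta) P(\text{pair} \mid f)$,
  a weighted logistic M-step, and frequency updates from expected counts,
  iterated to a log-likelihood tolerance of 1e-6 (cap 200). Haplotypes
  below the pooling tolerance are merged into one POOLED column that
  participates in the fit but is never itself declared a significant
  haplotype. The two profiles mirror the two classical implementations.
  Profile `"glm"` floors the tolerance at 0.001, lets the likelihood
  plateau under separation (reporting the resulting large-coefficient,
  large-SE Wald tests), and takes standard errors from the complete-data
  weighted-IRLS covariance of the final M-step — the naive EM-GLM shortcut
  that ignores phase and frequency uncertainty. Profile `"hapassoc"`
  allows tolerance 0, flags separation as non-convergence (that failure is
  *reported*, never silently ignored; non-converged fits carry no
  p-values — and with many rare haplotypes at modest sample sizes it fails
  often, by design), and uses improved standard errors: the regression
  block of the inverse observed information of the joint likelihood
  (numerical Hessian in $(\beta, \log f_k/f_1)$ coordinates, with
  frequencies collapsed to numerical zero held fixed).
- `single_snp_scan()` is the first stage of a two-stage alternative:
  per-SNP logistic regression Wald tests at a 5% significance level,
  with monomorphic SNPs reported as `NA`.

## Scan orchestration and permutation

`run_scan()` recomputes the diplotype expansion and EM frequencies per
window, runs the requested methods, and isolates failures (a window with
a single haplotype raises "no contrast" for LBL; the scan continues and
the failure is logged). Per-window seeds are derived deterministically
from the global seed and the window start, so a parallel execution would
reproduce the serial results. `fpr_summary()` computes, per method, the
number of significant haplotypes over the number reported across all
windows — non-converged results excluded from both numerator and
denominator; the overall score test is summarized separately with windows
as the denominator, and an empty denominator yields `NA`, not 0.
`permutation_fpr()` permutes case-control status uniformly among retained
individuals (excluded individuals are not permuted), defaulting to a
single permutation for fidelity to the original design; with `R > 1` the
per-permutation rows and their mean are both reported, which tightens the
estimate at the cost of more computation.

## The synthetic cohort generator

`simulate_cohort()` generates the kind of data this analysis assumes:
a pool of 5-SNP haplotypes dominated by rare members — the default pool
has 12 haplotypes, two common (0.46, 0.40) and ten rare (0.004 to 0.02,
several at or below 0.005), echoing the frequency spectrum of
exome-derived blocks; diplotypes drawn with the HWD parameter (default
$d = 0$); disease assigned by the logistic model with planted
per-haplotype log odds ratios and optional covariate main/interaction
effects (intercept −1.5, baseline prevalence about 18%); and case/control
quotas filled retrospectively (default 456/1395, a 1:3 ratio in a cohort
of 1851). Blood pressures and medication flags are synthesized so the
case definition round-trips exactly: cases get SBP in (141, 200) or
medication = yes; controls get sub-threshold pressures with medication no
or missing. Genes longer than one window are composed of independent
5-SNP segments, so between-segment linkage disequilibrium is *not*
emulated — a deliberate simplification: within-window LD structure is what
the methods consume. Missingness is injected per SNP at configured rates.

What passing tests on these cohorts do show: calibration and ranking of
the methods in the rare-haplotype regime the generator emulates. What
they do not show: behavior under population stratification, genotyping
error, long-range LD, or covariate-haplotype dependence (the interaction
model assumes independence), none of which the generator produces.

## Numerical choices and experiment sizes

- EM: tolerance 1e-8 on the log-likelihood, 1000-iteration cap,
  frequency pruning at 1e-8, all configurable.
- LBL: test-scale chains 10000/3000; null interval $\log 1.1$; BF cap
  100; intercept prior N(0, 2); Dirichlet proposal concentration 2000,
  adapted during burn-in.
- The bundled calibration experiment uses 50 independent null
  single-window cohorts of n = 600 (150 cases / 450 controls) — enough
  windows (~600 haplotype tests) to separate a 2% from a 7% false-positive
  proportion — and the power experiment 20 replicates of n = 2000 with a
  planted haplotype at frequency 0.005 and odds ratio 3; both sizes were
  chosen as the smallest that give stable proportions for the comparisons
  they support.
- Degenerate inputs: single-haplotype windows error ("no contrast");
  all-case or all-control labels error; monomorphic SNPs give `NA`;
  empty window sets give empty reports with a warning.

## Known limitations

Binary phenotypes only (the retrospective model has no continuous-trait
analogue here); no multi-covariate adjustment; no LD-aware window
definition (fixed-width sliding windows only); no family data; the
EM-GLM standard errors use a numerical information matrix rather than the
classical analytic approximation; and the permutation assessment, as in
the original design, estimates false-positive proportions over correlated
windows — useful qualitatively, not a formal type-I error rate.
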