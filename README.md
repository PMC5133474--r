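# rhapscan

Gene-wide **rare-haplotype association scans** for case-control studies:
sliding windows of SNPs, EM haplotype reconstruction from unphased
genotypes, a **retrospective-likelihood logistic Bayesian LASSO (LBL)**
with Bayes-factor tests that can assess individual rare haplotypes, the
standard frequentist comparators (haplotype score test, EM-GLM Wald tests
with pooling, single-SNP logistic scan), and a permutation module for
false-positive assessment. A synthetic-cohort generator produces the
rare-haplotype-rich case-control data this analysis assumes, for
calibration and power studies.

## Who this is for

Statistical geneticists analyzing dense (e.g. exome) SNP panels where most
variants — and almost all haplotypes built from them — are rare. In that
regime, score and Wald haplotype tests either pool rare haplotypes away or
produce inflated false-positive rates; hapassoc-style EM-GLMs often fail
to converge. LBL shrinks unassociated effects through double-exponential
priors, keeping false positives low while individual rare haplotypes
remain testable.

## The model

For a window of `w` SNPs (default 5, step 1), each individual's unphased
genotype expands into its compatible unordered haplotype pairs; EM
estimates haplotype frequencies `f`. LBL then models haplotypes given
disease status (matching case-control ascertainment):

    P(Z = z | Y = y) = P(y | z) P(z | f, d) / Σ_z' P(y | z') P(z' | f, d)

with diplotype probabilities allowing Hardy-Weinberg disequilibrium
(`P{(k,l)} = 2(1−d) f_k f_l`, `P{(k,k)} = d f_k + (1−d) f_k²`) and
logistic disease odds `logit P(y=1|z) = a + x(z)'β`, where `x(z)` counts
copies of each non-baseline haplotype. Priors: `β_j ~ DE(0, λ)`,
`λ ~ Gamma(a_λ, b_λ)` (the Bayesian LASSO), flat Dirichlet on `f`,
uniform `d` on its admissible range, proper normal on `a`. MCMC is
Metropolis-within-Gibbs with a C++ core. Evidence per haplotype is the
Bayes factor for `|β| > ε` (default `ε = log 1.1`); **BF > 2** declares
significance, values above 100 are reported as ">100".

## Worked example

```r
library(rhapscan)

# a synthetic cohort: 456 cases / 1395 controls, one 5-SNP window,
# a planted rare haplotype (frequency 0.005) with odds ratio 3
cfg <- sim_config(beta = c("11010" = log(3)))
sim <- simulate_cohort(cfg, seed = 11)

g  <- filter_snps(recode_minor(sim$genotypes))$genotypes
rep <- run_scan(g, sim$pheno$status, methods = c("lbl", "score", "glm"),
                lbl_ctrl = lbl_control(n_iter = 10000, burn_in = 3000),
                seed = 1)
subset(rep$results, hap == "11010",
       select = c(method, freq, OR, bf, p_value, significant))
```

```
# A tibble: 3 × 6
  method    freq    OR    bf p_value significant
  <chr>    <dbl> <dbl> <dbl>   <dbl> <lgl>
1 lbl    0.00505  2.34  2.54 NA      TRUE
2 score  0.00505 NA    NA     0.0535 FALSE
3 glm    0.00505  2.99 NA     0.0194 TRUE
```

The planted haplotype (18 copies among 3702 chromosomes) is declared
significant by LBL — posterior-mean odds ratio 2.3 against a truth of 3,
Bayes factor 2.5 above the threshold of 2 — while the score test just
misses at p = 0.054. Detection of an effect this rare is not certain at
this sample size: across replicates LBL finds it in roughly 60% of
cohorts. The deeper difference between the methods shows up under the
*null*: permuting the phenotypes (`permutation_fpr()`) and rescanning,
LBL's significant/reported proportion stays near 2% while the score
test runs several-fold higher on rare-haplotype-rich windows.

A thin command-line front end (`inst/cli/rhapscan.R`) exposes
`simulate`, `scan` and `permute` subcommands over the same functions.

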