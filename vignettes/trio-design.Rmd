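---
title: "Separating genetic transmission from genetic nurture with trio polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genetic transmission from genetic nurture with trio polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design

A parental characteristic that predicts a child outcome can do so through two
very different mechanisms: the parent transmits half of their alleles to the
child (*genetic transmission*), or the parent's genotype shapes the rearing
environment the child grows up in (*genetic nurture*, an indirect genetic
effect). Observational parent–child associations cannot tell these apart.

With genotyped mother–father–child trios they can. Let $G_m$, $G_f$, $G_c$ be
standardized polygenic scores for one parental factor. The package fits

* the **unadjusted model** — child outcome on one family member's score, and
* the **trio model** — child outcome on all three scores jointly:

$$y = c\,G_c + m\,G_m + f\,G_f + \text{covariates} + \varepsilon .$$

Conditioning on the child's score blocks the transmitted-allele pathway, so
$m$ and $f$ estimate nurture, and $c$ estimates the direct genetic effect.
Under random mating the population slope of the unadjusted parental model is
$m + c/2$, because the parent–child score covariance is $1/2$. The difference
$\Delta\beta = \beta_{\text{unadjusted}} - \beta_{\text{trio}}$ therefore
converges to $c/2$ when nurture is absent, and a significant $\Delta\beta$
together with a null adjusted parental estimate is the signature of pure
transmission. All fits control for child sex and birth year, and coefficients
are reported in outcome-SD units (outcome and scores standardized).

`classify_mechanism()` encodes the decision rule: an FDR-surviving adjusted
parental estimate is called *genetic nurture* (*both* if the attenuation test
is also significant); an FDR-surviving unadjusted estimate with significant
attenuation and a null adjusted estimate is *genetic transmission*; an
unadjusted association with neither is flagged as possibly power-limited;
anything else is *no association*.

## What the simulator emulates

Real trio cohorts with linked phenotypes are access-restricted, so the
package pairs the estimator with a generative model rich enough to test every
stage by parameter recovery:

* **Genotypes.** Unlinked biallelic SNPs in Hardy–Weinberg proportions;
  effect-allele frequencies uniform on a configurable interval (default
  0.05–0.5). Causal effects are Normal draws rescaled so the raw causal score
  has population variance 1, making the latent score an SD-unit quantity and
  the paths `c`, `m`, `f` directly interpretable.
* **Transmission.** One allele per parent per locus; a heterozygote transmits
  the effect allele with probability 1/2 independently across trios and loci.
  This yields the 1/4–1/2–1/4 segregation law for het×het crosses, a
  parent–child score covariance of $(1+a)/2$ and a child score variance of
  $1 + a/2$ on the parental-SD scale (spousal score correlation $a$).
* **Assortative mating.** Spouses are paired by the rank of their jittered
  scores (or of a noisy phenotype proxy carrying 50% score variance). For
  rank pairing of independently jittered standard-ish scores the realized
  spousal correlation is $1/(1+\lambda^2/\sigma^2)$, so the jitter SD is set
  to $\sigma\sqrt{1/a - 1}$ in closed form; the suite checks the realized
  correlation lands within ±0.02 of the target at n = 20,000.
* **Stratification.** Two demes with Balding–Nichols-style frequency
  divergence controlled by one scalar, plus an optional per-deme phenotype
  offset. Deme labels are oriented so deme 2 always carries the higher mean
  latent score; a positive `deme_pheno_shift` is then an aligned confounder
  with a reproducible sign — the configuration in which stratification
  inflates nurture estimates, which is what the bias tests exercise. (With an
  unoriented label the alignment, and hence the sign of the bias, would be a
  coin flip per panel.)
* **Phenotype.** The linear path model plus sex, birth-year and deme effects
  and Gaussian noise, standardized to mean 0, SD 1 afterwards. The default
  `noise_sd = "auto"` solves for the residual SD that makes the *population*
  phenotype variance 1, so post-hoc standardization is a population no-op and
  identities like $\beta_{\text{unadjusted}} = m + c/2$ hold on the reported
  scale without rescaling.
* **GWAS weights.** Estimated effects are true effects plus Normal error with
  SE $1/\sqrt{N \cdot 2p(1-p)}$ and two-sided normal p-values; `gwas_n`
  controls score quality, and `Inf` gives noise-free weights. Null-variant
  p-values are uniform by construction.
* **Missingness.** Auxiliary variables with configurable correlation to the
  phenotype; the missingness probability is logistic in the auxiliary mean
  (MAR given auxiliaries), with the intercept solved numerically so the
  marginal rate matches `missing_rate`. Slope 0 gives MCAR.

What it deliberately does **not** emulate: linkage disequilibrium (scores are
built from unlinked loci, so no clumping is implemented), X-chromosome or
imprinting effects, sibling or grandparental indirect effects, and binary or
liability-scale outcomes. Passing recovery tests on this generator shows the
estimator chain is correct under its own assumptions; it does not certify
robustness to LD structure or to score portability problems in real data.

## Score construction

`compute_threshold_scores()` computes, per p-value threshold, the weighted
sum of effect-allele dosages, aligning the genotype file's counted allele to
the summary-statistics effect allele (counted = other allele maps dosage
$g \to 2-g$; variants matching neither allele are dropped with a log line).
`prs_pc()` standardizes the threshold columns and takes their first principal
component, sign-aligned to correlate non-negatively with the mean
standardized score and re-standardized — a composite that uses all thresholds
without picking one by validation. The default ladder is
5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1 and is configurable.

In the pipeline the PC loadings are estimated once on mothers, fathers and
children pooled. Role-specific loadings would put parents and children on
incommensurable scales; pooling keeps one scale so the trio coefficients are
comparable across family members.

Scores are then residualized on ancestry PCs (left singular vectors of the
column-standardized pooled dosage matrix; 10 by default) and standardized.
Residualize-then-standardize guarantees unit-SD predictors in the
regressions; the residuals are exactly uncorrelated with every included
covariate, and the operation is idempotent. Batch labels with a single
member are merged into an "other" level before expansion, since a
one-member indicator would make the residual SD undefined under robust SEs.

## Outcome scoring and missing data

The 18-item four-point scale is scored as a total (range 18–72) and two
9-item subscales (9–36). Respondents with fewer than half the items are
excluded; with 9–17 items the total is prorated as the person-mean × 18 (the
common convention for this instrument — a strict complete-case flag is
available), and subscales require 5 of 9 items analogously.

Missing outcomes are multiply imputed from polygenic scores and auxiliaries
by predictive mean matching under a Bayesian linear model: per imputation the
residual variance and coefficients are drawn from their posterior, and each
missing case receives the observed outcome of one of the 5 nearest observed
cases by predicted value. Only the outcome is ever incomplete here (scores
exist for everyone by construction), so the chained-equations system reduces
to a single equation. The default is M = 20 imputations. Estimates are pooled
by Rubin's rules — pooled variance = within + (1 + 1/M)·between — with
Barnard–Rubin small-sample degrees of freedom. The suite verifies pooling
exactly against a hand-worked two-imputation example, checks MCAR pooled
estimates against the complete-data fit, and checks that under informative
attrition the pooled estimates are closer to the generative truth than
complete-case estimates on average.

## The attenuation test

`delta_beta()` estimates $\Delta\beta$ on the identical row set for both
models. The default is a paired nonparametric bootstrap (B = 1000): trios are
resampled, both models refit per resample, the SE is the bootstrap SD and the
p-value its normal approximation; a percentile CI and a centered empirical
p-value with the $(1 + \#\text{exceedances})/(B+1)$ convention (no exact
zeros) are also reported. The analytic alternative stacks the two estimating
equations and uses the influence-function covariance of the coefficient pair
— the two agree within a factor of two on the $-\log_{10} p$ scale for
moderate signals, which the suite checks. Under imputation the analytic
method is computed per imputation and the deltas pooled by Rubin's rules.

Standard errors are heteroskedasticity-robust (HC1) by default with a
classical option; under the homoskedastic generator the two coincide to
Monte-Carlo accuracy, so the choice is conservative rather than consequential
here.

FDR control uses Benjamini–Hochberg step-up, applied within each model family
(the motivating design has 36 tests per family: 12 parental factors × 3
family members); the suite fuzzes the implementation against a brute-force
step-up oracle and checks empirical FDR control at that family size. Whether
the original analyses pooled families jointly is not documented precisely;
per-family application is the default and a joint family is a one-liner
(`bh_fdr` on the concatenated p-values).

## Numerical and reproducibility choices

* All randomness flows from one global seed through stage-specific derived
  streams (`derive_seed`), so changing one stage's parameters never perturbs
  another stage's draws, and identical configs give byte-identical cohorts
  and result tables.
* Degenerate inputs fail loudly with classed conditions: constant scores,
  all-constant threshold columns, perfectly explained residuals, rank
  deficiency among trio scores (the collinear terms are named), p-values
  outside (0, 1].
* True scores are standardized against the pooled parental sample; children
  use the same transformation, so parent–child covariances are on the
  parental-SD scale and the child variance under assortment is visible
  rather than normalized away.
* Item responses written by the cohort writer are derived by thresholding
  noisy item-level copies of the continuous trait into 1–4 bins with a
  right-skewed marginal (most children rated low), so file-level item
  scoring, prorating and exclusion can be exercised end-to-end.

## Known limitations

The estimator inherits the design's blind spots: with imperfect scores,
assortative mating inflates nurture estimates (the suite demonstrates this:
with heritable weight noise and spousal score correlation 0.2, mean nurture
estimates are pushed above zero while the direct-path conclusion is
preserved), and uncorrected stratification does the same until scores are
residualized on ancestry PCs. Genetic nurture estimates also absorb any
familial environment correlated with parental genotype (sibling and
grandparent effects are not modelled). Score measurement error attenuates
the child path estimate below the generative `c`; the recovery guarantees
hold for perfect scores.

Test and recovery problem sizes were chosen as the smallest that make the
Monte-Carlo bands informative: 200 cohorts of 5,000 trios for recovery and
coverage, 50,000 trios for the population attenuation identity, 100
replicates for the assortment bias sign test, 50 for the attrition
comparison, and 10,000 replicates of 36 tests for FDR calibration.
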