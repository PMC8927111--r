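---
title: "Familial aggregation and variance components with kinherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation and variance components with kinherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinherit)
```

## The scientific problem

Common conditions such as depression, anxiety, obesity and substance use run
in families and co-occur within persons. Two complementary family-based
statistics quantify this:

* the **recurrence risk ratio** `lambda_R`: the prevalence of a phenotype
  among relatives of affected individuals divided by a reference prevalence.
  Same-trait `lambda_R` measures familial aggregation; cross-trait
  `lambda_R` ("your relative is obese, are you more likely to be
  depressed?") measures familial co-aggregation.
* **pedigree-based variance components**: the animal model
  `y = X beta + a + e`, with `a ~ N(0, sigma2_a * A)` and
  `e ~ N(0, sigma2_e * I)`, where `A` is the additive genetic relationship
  matrix expected from the pedigree. Narrow-sense heritability is
  `h2 = sigma2_a / (sigma2_a + sigma2_e)`; in the bivariate model the genetic
  correlation is `r_G = sigma_AxAy / sqrt(sigma2_Ax * sigma2_Ay)`, and the
  phenotypic and residual correlations `r_P`, `r_E` follow from `G + R` and
  `R`.

kinherit implements both pipelines end to end on pedigree + phenotype data,
with a liability-threshold cohort simulator providing ground truth for every
stage.

## Pedigrees and the relationship matrix

Pedigrees are read from PLINK `.fam`, LINKAGE pre-makeped or CSV files.
Family labels are recomputed as connected components of the parent/partner
graph rather than trusted from the file, because families are the
exchangeable unit for all clustered inference downstream. Generation indices
are longest-path depths from the founders, which guarantees parents precede
offspring in the tabular recursion

```
a_ii = 1 + a_{father(i), mother(i)} / 2
a_ij = (a_{j, father(i)} + a_{j, mother(i)}) / 2 .
```

`A` is computed family block by family block (it is block diagonal by
construction), densely below 2,000 individuals and assembled as a sparse
symmetric matrix above; the entries are identical. When a subset of
individuals is requested, the matrix is computed over the full pedigree and
restricted afterwards, so unphenotyped connecting ancestors still transmit
relatedness.

Relative pairs: first-degree means parent-offspring or full sibling (both
parents shared and recorded). Half-siblings, avuncular and grandparental
pairs are deliberately "other". Spouses are primarily defined by a shared
child — always derivable from a pedigree file — with optional explicit
partner links for childless couples; whether childless partners count as
spouses is a user decision, since cohort pedigrees rarely say. Spouse pairs
that are also blood relatives are flagged and excluded from spouse analyses.

`geneDropRelatedness()` is an independent Monte-Carlo check: two allele
labels per founder, transmitted uniformly at random, with expected
identity-by-descent sharing estimated over hundreds of thousands of
replicates. The tests compare every tabular entry against this oracle at its
Monte-Carlo standard error. One statistical note: with thousands of entry
comparisons, a per-entry three-standard-deviation band is exceeded by a few
entries purely by chance (about 0.27% of them), so the test suite asserts
that at least 99% of entries fall within three MC standard deviations and
all within five, rather than pretending a simultaneous three-sigma bound is
attainable.

## The recurrence module

Two estimators are reported, because the verbal definition of `lambda_R` and
regression adjustment target different denominators:

* `lambdaNaive()`: prevalence among exposed (has an affected relative in the
  chosen set) over prevalence in the **total analysis population**, the
  classic definition. The exposed-vs-unexposed ratio is reported alongside.
  Confidence intervals come from a bootstrap that resamples whole families
  (2,000 resamples by default, seeded).
* `lambdaAdjusted()`: log-link prevalence-ratio regression of the outcome on
  exposure plus age, age squared and sex, using a Poisson working likelihood
  with constant time at risk and a robust sandwich variance clustered on
  family. The exponentiated exposure coefficient is the exposed-vs-unexposed
  prevalence ratio — the same estimand a proportional-hazards model with
  constant follow-up returns, which is why this implements the
  "modified Cox" approach without survival machinery. No small-sample
  cluster adjustment is applied; this keeps the estimator exactly equal to
  the ordinary heteroscedasticity-robust sandwich when every cluster has
  size one, and the difference is O(1/families) otherwise.

Exposure construction never lets an individual's own outcome influence its
exposure; individuals none of whose relatives have an observed exposure
trait are dropped and counted. Individuals contribute both as probands and
as relatives — family-clustered variances absorb the double use.
Significance is two-sided at 0.05 with no multiplicity correction, matching
standard practice for these descriptive family analyses.

## The variance-component module

`remlUnivariate()` and `remlBivariate()` maximise the restricted
log-likelihood by **average-information (AI) REML**. Because `A` (restricted
to phenotyped members) is block diagonal by family, each family block is
eigendecomposed once; in the rotated basis the covariance is diagonal
(univariate) or 2x2-block diagonal (`d_k * G + R`, bivariate), so every
iteration costs O(n) vector arithmetic regardless of cohort size. Pairs with
one trait missing are handled by the joint likelihood over the observed
entries via per-family dense algebra — not listwise deletion.

Numerical choices:

* Parameters are the raw (co)variance components. Positive
  semi-definiteness is enforced by cone control — step-halving of AI
  proposals plus an EM-type natural-gradient fallback
  (`G <- G + (2/n) G S G`) — rather than a log-Cholesky transform; the AI
  matrix is natural on the component scale, and cone control gives the same
  constraint without chain-rule bookkeeping through a reparameterization.
* Starting values: half the residual phenotypic variance to each component;
  covariances start at half the residual covariance.
* Convergence: |change in restricted logL| < 1e-8 **and** free-gradient norm
  < 1e-6, within 200 iterations. At a constrained optimum on the PSD
  boundary (e.g. `r_G = 1` for a trait duplicated with noise) the free
  gradient cannot vanish, so three consecutive iterations with negligible
  likelihood gain also terminate, with a boundary flag. Boundary estimates
  are flagged, never silently clamped.
* Traits are standardised internally to unit variance and all results mapped
  back, making the fit invariant (to ~1e-8) under affine rescaling.
* If `A` over the phenotyped individuals is numerically the identity,
  `sigma2_a` and `sigma2_e` are confounded: the fit warns, returns the
  boundary and sets a flat-likelihood flag instead of wandering.

Standard errors come from the delta method on the inverse AI matrix.
Significance of `h2` uses the restricted likelihood ratio against
`sigma2_a = 0` referred to the boundary mixture
`0.5 * chi2_0 + 0.5 * chi2_1`. The `r_G` test against 0 is Wald on the
Fisher-z scale; the test against 1 is Wald on the raw scale, because the
Fisher transform is infinite at 1, and it is skipped when the estimate is at
the boundary. Binary traits are never fed to REML — observed-scale
liability conversions are out of scope — so heritabilities are reported for
continuous traits only.

## The simulator and what it does (not) emulate

`simulateCohort()` generates trio, nuclear or three-generation families.
Founders draw additive genetic vectors from `MVN(0, G)`; offspring receive
the parental mean plus a Mendelian-sampling deviation
`MVN(0, G/2 * (1 - (F_f + F_m)/2))` — the inbreeding correction is kept
although the built-in structures never produce inbred parents. Residuals are
`MVN(0, R)`. Continuous phenotypes add age, age-squared and sex effects;
ages are drawn per generation (defaults 65 +/- 8, 40 +/- 6, 15 +/- 4 years)
so those effects are estimable. Binary traits threshold the standardized
total liability (before fixed effects) at the standard-normal quantile of
their prevalence; age-varying prevalence is deliberately not modelled.

Spouse resemblance has two separable mechanisms, because familial data alone
cannot apportion them: a couple-shared residual component, and assortative
mating by Gaussian rank-matching — one sex's liabilities are paired against
ranks of a correlation-rho noisy copy of the other's, hitting the target
spouse correlation without changing either marginal distribution.

`exampleCohortConfig()` encodes the study conditions used throughout the
tests and the acceptance script: heritabilities 0.53 (BMI-like), 0.25
(depression sum score), 0.30 (anxiety sum score), 0.35 (daily alcohol);
genetic correlations 0.94 between the psychiatric scores, 0.26 between BMI
and each psychiatric score, and negative correlations of alcohol with BMI
(-0.14) and the psychiatric scores (-0.16, -0.10); binary diagnosis twins of
each trait thresholded at prevalences 15.04%, 3.44%, 7.74% and 15.57%; and
assortative mating at 0.25 on the BMI-like trait. The anxiety heritability
and the residual depression-anxiety correlation (0.30) are plausible filled
values where the emulated design gives no number.

What passing tests consequently do **not** show about real cohorts: no
shared-household or dominance variance, no gene-environment interaction, no
age-dependent prevalence or onset, missingness only missing-at-random, and
sum scores simulated directly as Gaussian traits rather than built from
items. Estimates on real data inherit all the usual caveats of the animal
model (e.g. common environment inflating `sigma2_a` when not modelled).

## The pipeline

`runStudy()` chains descriptive statistics (mean +/- sd, or median and IQR
when |skewness| > 1; prevalences for binary variables), aggregation and
co-aggregation per relative set, univariate heritabilities and all bivariate
correlations, and a complete-vs-missing demographic comparison with
standardized mean differences. Per-analysis failures are recorded in their
result rows and the run continues. All randomness flows from one seed
through derived streams, and reports carry no timestamps, so a rerun is
payload-identical. `subsampleSensitivity()` redraws whole families up to the
target size — subsampling individuals would break pedigrees — reruns
everything, and reports the share of significant findings lost per analysis
class.

## Problem sizes used by the test suite

The simulation scales are the package's own choices: parameter recovery at
3,000 nuclear families (10 seeds per heritability value), type-I error of
the `r_G` test over 200 replicates of 400 families, bootstrap coverage of
the null `lambda_R` over 500 replicates of 400 families, power of the
adjusted `lambda_R` over 100 replicates of 2,000 families, and the
sign-pattern study at 1,500 three-generation families. Where a test compares
many noisy quantities at a per-comparison banding (the gene-dropping oracle,
per-seed recovery), the assertion is multiplicity-aware: the stated band
must hold for the expected share of comparisons and a wider hard cap for all
of them, since demanding thousands of simultaneous three-sigma events would
reject a correct implementation.

## Known limitations

Only additive genetic and independent residual components are fitted (no
household, maternal or dominance terms); binary-trait heritability on the
liability scale is not provided; `lambda_R` has no age-of-onset dimension —
the cross-sectional prevalence ratio is the estimand; and the assortative
and shared-environment spouse mechanisms, while both implemented, cannot be
distinguished from each other by the statistics this package reports.
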