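---
title: "Methods: chromosome arm-specific telomere length analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome arm-specific telomere length analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods in `armtel`, the
modelling choices that were genuinely open, and what the package's
synthetic validation does and does not establish about real data.

## The data and its structure

A chromosome-specific telomere length (csTL) call table carries one
row per allele cluster: a sample, a chromosome arm label, an allele
index, the cluster's TL estimate (the 75th percentile of its
supporting reads' telomere lengths, in bp), a telomere-variant-repeat
(TVR) length, and the number of supporting reads. The diploid genome
has 92 telomeric sites (22 autosomal pairs x 4 arm copies + 4
sex-chromosome arms); after averaging the two homologous copies of an
arm, each person has up to 48 csTL values. Quality control drops
estimates below 100 bp, negative TVR lengths (artifacts of the
telomere/subtelomere boundary search) and calls mapping ambiguously to
more than one arm. The acrocentric short arms (13p, 14p, 15p, 21p,
22p) share pseudo-homologous sequence that prevents unambiguous
telomere assignment, and the sex-chromosome arms are unbalanced
between sexes; both sets are excluded from association analyses,
leaving 39 autosomal analysis arms. The modeling substrate is the long
table of person x arm records with covariates.

## The crossed random-effects model

csTL records are doubly clustered: every individual contributes to
many arms and every arm to many individuals. The model is

$$y_{ia} = x_{ia}'\beta + u_i + v_a + e_{ia}, \qquad
u_i \sim N(0, \sigma^2_{ind}),\;
v_a \sim N(0, \sigma^2_{arm}),\;
e_{ia} \sim N(0, \sigma^2_e),$$

with crossed (not nested) random intercepts. Fitting maximizes the
profiled ML or REML objective over relative covariance parameters
$\theta$ (random-effect SDs relative to $\sigma_e$): $\beta$ and
$\sigma^2_e$ are profiled out analytically, and the remaining
parameters are optimized quasi-Newton (`nlminb`) with a log
parameterization of the diagonal entries, which enforces
non-negativity without constrained optimization. All linear algebra
runs through the penalized normal equations
$A = \Lambda' Z'Z \Lambda + I$ in the q-dimensional random-effect
space: a dense Cholesky path for small q (at most 500 levels, where
dense factorization is faster than sparse bookkeeping) and a sparse
`Matrix::Cholesky` path otherwise. The n x n marginal covariance is
materialized only in the test suite's independent oracle, which
evaluates the Gaussian (restricted) likelihood directly from the dense
covariance and must agree with the profiled objective to 1e-6.

The age-by-arm interaction model adds a random slope of age for the
arm factor — a slope variance and a slope-intercept covariance, so the
likelihood-ratio test against the intercepts-only model has 2 degrees
of freedom. The slope covariate is centered internally; otherwise the
intercept-slope correlation approaches -1 and the optimizer stalls
along a ridge. Predicted per-arm slopes are the fixed age coefficient
plus each arm's slope BLUP.

Numerical details worth recording:

- The penalized residual sum of squares is floored at 1e-10 to keep
  the profiled log impossible to NaN on degenerate inputs.
- Convergence requires the optimizer's own criterion or a central-
  difference gradient norm below 1e-2 relative at the optimum; fits
  carry `converged` and `boundary` flags (a log-scale parameter below
  -11.5, i.e. a variance ratio under ~1e-10, is reported as a zero
  boundary).
- Collinear fixed designs are rejected up front, naming the aliased
  columns, rather than silently dropping them.
- Record order and level labels do not affect estimates beyond
  floating-point summation order; the tests assert this.

## Variance partitioning and tests

The fixed-effects share is the sample variance of $X\hat\beta$ (sample
rather than population denominator; at tens of thousands of records
the difference is negligible) divided by the total
$T = \mathrm{Var}(X\hat\beta) + \hat\sigma^2_{ind} + \hat\sigma^2_{arm}
+ \hat\sigma^2_e$, so the four shares sum to one by construction.
Single-covariate contributions (marginal R²) come from a model with
that covariate alone plus both random intercepts, compared by ML LRT
against the intercept-only model. Random-effect LRTs compare REML fits
with identical fixed parts; fixed-effect LRTs compare ML fits. Plain
$\chi^2$ reference distributions are used throughout, including for
variance components, where the null lies on the boundary of the
parameter space; the 50:50 mixture correction would halve those
p-values, so the plain-$\chi^2$ convention is conservative and is the
one reported. P-values that underflow double precision are accompanied
by an exact log10 p-value computed on the log scale.

Batch can enter three ways — fixed effect, extra crossed random
intercept, or pre-adjustment by residualizing csTL on batch means —
and the covariate coefficients should agree in sign and closely in
magnitude across the three; a property test asserts this on synthetic
data. The batch reference level is the largest batch; ancestry,
sex and smoking use AFR, female and never-smoker references.

## Per-arm analyses

Arm-wise associations are ordinary least squares per arm (each arm fit
on its own records), reported without multiple-testing adjustment
across the 39 arms — the per-arm p-values are descriptive, and the
cross-arm inference is carried by the exact binomial direction test:
with k of n arms in the expected direction, the one-sided P is the
binomial tail $\sum_{j \ge k} \binom{n}{j} 2^{-n}$. The reported
interval is an exact one-sided (Clopper-Pearson) 95% lower bound with
the upper bound fixed at 1, which matches the one-direction
alternative; the two-sided-convention bound is available via
`ci_sided = "two"`. For 31 and 26 of 39 arms the one-sided bound
rounds to 0.66 and 0.52 respectively; at 39 of 39 it is
$0.05^{1/39} \approx 0.926$.

## Batch adjustment of average TL

Short-read average-TL estimates carry technical variance aligned with
sequencing batch. The adjustment regresses average TL on the leading
principal components of a binned genome-wide depth matrix (bins
z-scored before the SVD — depth bins differ in scale, and without
standardization high-variance bins dominate the rotation; the choice
is exposed as `scale.`). The number of components k is data-driven:
for each k in 0..50 the residuals' absolute Pearson correlation with
age is computed, and the k maximizing it wins, smallest k on ties.
k = 0 (mean-centering only) is included in the grid, so an
artifact-free input selects no adjustment. The rationale for the age
criterion: age is the strongest established TL correlate, so removing
technical components should sharpen, never blur, the age correlation.

## The synthetic-cohort generator

Real csTL cohorts of this kind are access-controlled, so the package
ships a generator that reproduces the statistical structure the
analyses assume, with every stage's expected behavior testable:

- **Variance fractions.** Total csTL variance (`total_sd`^2, default
  1500^2 bp²) is partitioned by configured fractions among individual
  intercepts, arm effects, batch offsets, age, sex, smoking, BMI,
  ancestry, and residual (the remainder). Each drawn component is
  centered and rescaled to its exact in-sample share, and effect sizes
  are calibrated against realized covariate variances. This makes the
  configured fractions hold exactly in each simulated cohort rather
  than only in expectation — the right property for parameter-recovery
  validation, where estimator error, not generator sampling noise,
  is the quantity under test. With only 39 arm levels, an
  unstandardized arm effect would carry ~23% relative sampling spread
  and recovery checks would mostly measure that.
- **Scale.** The default total SD of 1500 bp keeps Gaussian true TLs
  essentially always positive (values are floored at 50 bp; under the
  defaults the floor binds for ~0.3% of sites). The default grand mean
  is 4200 bp. The arm profile spans 2-6 kb in raw form and encodes the
  reported ordering (3p, 4q, 13q long; 3q, 16q, 20q, 17p, 12p short);
  its deviations are rescaled so the configured arm fraction is met,
  so the profile contributes ordering, not absolute spread.
- **Age slopes.** Arm-specific slopes follow
  $s_a = -b\,(m_a/\bar m)^{c}$ with coupling exponent c
  (default 1), so longer arms decline faster when c > 0, and b is
  calibrated so the age-attributable variance matches its fraction.
- **Batch-ancestry confounding.** Individuals are assigned to batches
  (center x platform x coverage tier) with per-batch ancestry mixing
  weights; one default batch is single-ancestry. The default ancestry
  causal effect is zero: with strong batch confounding the marginal
  ancestry contribution is batch-driven, which the decomposition
  reproduces, and a causal ancestry share would be unidentifiable from
  batch anyway. The within-batch ancestry proportions are free
  parameters of the design table.
- **Alleles and reads.** The two allele TLs of an autosomal arm are
  csTL ± d with d ~ N(0, `allele_sd` = 200 bp), a symmetric split
  that leaves the collapsed arm value equal to the generative csTL, so
  the configured fractions describe the collapsed quantity the models
  consume (an i.i.d. allele-level residual would halve its variance
  under two-allele averaging and decouple the configured fractions
  from the analysis substrate). Reads per site are Poisson with a
  tier-specific rate; read TLs add N(0, `read_noise_sd` = 500 bp)
  noise, floored at zero (a floor, not a truncated normal — floor
  events are rare at the default noise). Sequence content is not
  simulated: no FASTQ, no base-calling error model, no platform-
  specific repeat bias.
- **Disease.** Case status is Bernoulli with logistic probability in
  the chosen TL metric (per kb), inverting the logistic model the
  association analysis fits; the intercept is solved from a target
  prevalence at the metric mean.

What passing tests on this generator do *not* show about real data:
measurement error here is Gaussian and platform-unbiased, whereas ONT
base-calling produces systematically short csTL estimates; missingness
is driven only by Poisson coverage and the cluster-size threshold, not
by arm-specific mappability; true TLs are Gaussian rather than
right-skewed; and EHR-derived case definitions are replaced by clean
simulated labels. Recovery results validate the estimators under the
model's assumptions, not robustness to these violations.

## Pipeline conventions

Minimum supporting reads per allele cluster follows coverage tier
(4 for high-coverage batches above ~25x, 3 otherwise, configurable) —
the gap between 20x and 25x is not pinned by any published rule, so
the per-tier thresholds are plain configuration. Duplicate-platform
individuals resolve deterministically: PacBio beats ONT, more arm
estimates breaks PacBio ties, lexicographic order breaks exact ties.
The 75th percentile uses the type-7 (linear interpolation) definition,
pinned by an oracle test, since the upstream caller does not publish a
formula. Down-sampling keeps each read independently with probability
target/current coverage per sample, where telomeric coverage is mean
supporting reads per telomeric site; error and correlation are
computed only on arms present in both the thinned and full call sets.
Outlier exclusion for disease metrics is a single pass with bounds
from the pre-exclusion cohort. Disease models use raw csTL-derived
metrics with batch among the adjusters (rather than pre-adjusted
metrics), keeping one consistent adjustment pathway; both options
exist. The orchestration layer derives per-stage seeds from the master
seed by a stable hash so any stage can be re-run in isolation.

## Validation problem sizes

The suite's heavier checks run at sizes chosen to make the relevant
asymptotics visible while keeping a full test run in minutes:
variance-fraction recovery at 2000 individuals x 39 arms (where the
±0.02 recovery band is several estimator SEs wide for every graded
component), null LRT calibration over 500 replicates of 150 x 8
crossed layouts, dense-oracle equivalence at up to 200 records (dense
n x n algebra stays exact and fast), logistic odds-ratio recovery at
50,000 individuals (the Wald SE of log OR is ~0.012, well inside the
recovery band), coverage titration on a 50-person 30x cohort, and
slope-heterogeneity detection at 1500 x 39.

## Known limitations

The fitter supports crossed random intercepts for an arbitrary set of
grouping factors plus one random slope; it is not a general mixed-model
engine (no nested syntax, no non-Gaussian responses). Variance-
component LRT p-values are conservative at the boundary, as discussed.
Wald intervals are used for logistic odds ratios; profile-likelihood
intervals would differ noticeably only at small case counts, where the
per-arm models already carry a low-power flag. Haplotype identity is
not tracked: allele indices are unordered, so parent-of-origin
questions are out of reach. The depth-PC adjustment assumes technical
depth structure is low-rank and linearly related to the average-TL
artifact.
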