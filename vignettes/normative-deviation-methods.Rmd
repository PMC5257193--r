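---
title: "Normative trajectories and Mahalanobis deviation scores: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative trajectories and Mahalanobis deviation scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mahanorm)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters, what the synthetic generator does
and does not emulate, the numerical choices, and the known limitations. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The deviation framework

A longitudinal cohort consists of subjects in two groups — a clinical group
(ASD) and typically developing controls (TDC) — each contributing 1–4 scans
at increasing ages. Every scan carries a feature vector of regional DTI
medians: by default 19 white-matter tracts × four parameters (FA, MD, AD,
RD), so m = 76.

**Normative model (per feature).** On TDC scans only,

y_ij = f(age_ij) + β_coil · coil_ij + β_tmi · tmi_ij + u_i + ε_ij,

where f is a penalized cubic B-spline smooth, coil is the scanner head-coil
epoch, tmi the total motion index, u_i ~ N(0, σ_u²) a subject random
intercept for the repeated measurements, and ε_ij residual noise. The
normative prediction μ(age, covariates) is the *fixed-effects* part only.

**Residuals are marginal.** Deviations are observed − fixed-effects
prediction, with random intercepts excluded. ASD subjects have no random
effect under the TDC model, and scoring controls on conditional residuals
would make the groups incommensurable; the random intercept is estimated
only to de-bias the smooth. Because residuals are computed at each scan's
own (coil, tmi), deviations are covariate-adjusted.

**Mahalanobis distance.** With S the covariance of TDC scan-level residual
vectors, each scan's deviation is D_M = sqrt((x − μ) S⁻¹ (x − μ)ᵀ), and a
subject's representative value is the unweighted mean over their 1–4 scans
(no reweighting by scan count). Under identity covariance D_M is the
Euclidean norm; under the true covariance D_M² of null vectors is χ²_m.

**Covariance rows are scans, not subjects.** The reference S uses the 149
TDC scan residuals, not 57 subject means: subject-level rows could not
support m = 76 at all, and the per-scan distance is scored against scan-level
variation. Because m = 76 with ~149 rows is still ill-conditioned, the
default estimator shrinks toward the diagonal with an analytically chosen
intensity (the ratio of summed estimation variance of the off-diagonal
correlations to their summed squared magnitude, clamped to [0, 1]); `sample`
and `diagonal` estimators are available for sensitivity analysis. A feature
with zero residual variance aborts with its name rather than being silently
dropped — except in the fully degenerate case where *all* residuals are
numerically zero (a cohort lying exactly on one common curve), where every
deviation is zero by definition and scoring short-circuits to D_M = 0.

**Leave-one-out controls.** Scoring a control against curves fitted with
their own scans included would understate their deviation. For each TDC
subject, all m feature models and S are therefore re-estimated on the
remaining controls and the held-out subject's scans are scored against
those. The refits keep the knot locations, smoothing parameter λ and
variance ratio ρ at the full-fit values and re-estimate coefficients,
residual scales and S: re-running model selection inside each fold would add
selection noise to every held-out subject's score and buys nothing at
n − 1 = 56 subjects. LOO distances are optimistically larger than in-sample
ones; the acceptance suite measures that gap.

**Univariate standard scores.** For comparison with conventional analyses,
each feature also yields a per-scan signed score residual/σ̂, aggregated per
subject by the mean over scans; distribution comparisons use the absolute
value of the aggregate. σ̂ is the SD of marginal residuals (so it includes
between-subject spread), computed with an effective-degrees-of-freedom
correction, and the same smoother is used for the standard-score models as
for the distance models — a deliberate unification; the framework treats
"univariate" as the m = 1 restriction of the same machinery.

**Distribution analysis.** Subject-level distributions are compared by a
pooled-variance Student t (Welch optional), the variance-ratio
F = s²_ASD/s²_TDC with (n₁ − 1, n₂ − 1) df and a two-sided p, the
Bhattacharyya coefficient on 20 shared equal-width bins spanning the pooled
range (reported both on bin proportions, in [0, 1], and on raw counts),
exceedance fractions with strict inequality, and Pearson correlations with
phenotypes under pairwise deletion. Two-sided p-values throughout; no
multiple-testing correction is applied to the per-feature table.

## The smoother in detail

* **Basis**: clamped cubic B-splines on `n_knots = 8` quantile-placed knots
  of the TDC ages (basis dimension 10). Quantile placement follows the data
  density of an accelerated longitudinal design, which is age-uniform by
  construction here but need not be in real cohorts.
* **Penalty**: the exact Gram matrix of order-`penalty_order` derivatives
  (default 2), integrated by 3-point Gauss–Legendre quadrature per knot
  interval, which is exact for the piecewise polynomials involved. The null
  space therefore spans polynomials up to degree `penalty_order − 1`
  *exactly* — a coefficient-difference penalty would only approximate this
  under unequal knot spacing. As λ → ∞ the fit tends to the best
  covariate-adjusted polynomial of that degree.
* **Selection**: grid REML (default) or GCV over
  `lambda_grid = 10^seq(-4, 8, length.out = 25)`, after reparametrizing the
  penalized spline as fixed (null-space) plus i.i.d. wiggly effects. Grid
  search is deterministic and cannot step outside the declared range.
* **Variance components**: σ_u² and σ_ε² by method-of-moments on the
  marginal residuals (unbalanced one-way ANOVA on the subject grouping),
  iterated with the penalized GLS fit under the compound-symmetry working
  covariance V = I + ρJ (whose inverse is closed-form per subject). λ is
  re-selected only in the first three sweeps and then frozen: grid selection
  flips discretely with ρ, and freezing makes the remaining iteration a
  smooth, damped fixed-point update (tolerance 1e-5 on ρ, max 50
  iterations; non-convergence is an error naming the feature). Residuals
  that are numerically zero relative to the data scale force ρ = 0 rather
  than a quotient of rounding noise.
* **Extrapolation**: predictions outside the training age range clamp to
  the nearest boundary with a warning by default (`strict` mode errors).
  ASD scan ages span the TDC range by design, so clamping is rare and
  affects only range edges.

An independent cross-check: on simulated control cohorts the fitted curve
agrees with `mgcv::gam(y ~ s(age) + tmi + s(subject, bs = "re"), method =
"REML")` to a few thousandths RMSE (tested in the suite); `mgcv` is never
used in the computation path.

## The synthetic generator

The generator emulates the *design* of the motivating study — it does not
impersonate its data.

* **Visit structure** (default): 42/18/18/14 ASD and 15/14/19/9 TDC subjects
  with 4/3/2/1 scans, i.e. 92 ASD subjects with 272 scans and 57 TDC
  subjects with 149 scans (421 total; per-timepoint counts 92/78/60/42 and
  57/48/29/15). Baseline ages uniform on [3.1, 36.8] years; inter-scan gaps
  Gamma with mean 2.6 y and SD 0.9 y (the study reports interval summaries
  between 2.6 and 2.8 y; 2.6 is used as the design of record and the SD is
  a package choice in the reported range), so ages are strictly increasing
  by construction.
* **Trajectories**: f(age) = a + b·exp(−age/c) per feature — FA rising to an
  asymptote, diffusivities falling, fast early change slowing into
  adulthood. The real study fits nonparametric smooths; the exponential
  family reproduces that shape while giving closed-form truth for recovery
  tests. Defaults (e.g. FA: 0.55 − 0.25·exp(−age/5); MD: 0.75 +
  0.35·exp(−age/4), diffusivities in 10⁻³ mm²/s) carry small deterministic
  per-ROI offsets so features are distinct without extra randomness.
* **Noise**: per-feature subject random intercepts (SD 0.6× the residual
  SD); within-scan residual vectors drawn from a Kronecker-structured
  correlation — cross-ROI equicorrelation 0.2 times a within-ROI parameter
  block with FA–MD −0.4, FA–AD +0.2, FA–RD −0.5 and diffusivities mutually
  +0.6 — scaled by per-parameter SDs (FA 0.020, MD 0.022, AD 0.028, RD
  0.024). The signed block is a package choice (the study states only that
  the measures are "inherently correlated"); the magnitudes keep the matrix
  positive definite, which a uniform ±0.5 block would not be, and the
  Kronecker construction is PD whenever its factors are.
* **Covariates**: head coil flips from "pre" to "post" at a study-time
  changeover (2.5 y into a 7-y uniform entry window), so both epochs occur
  in both groups; TMI is lognormal, 25% higher in ASD by default. Both have
  small additive effects on every feature, signed per parameter.
* **ASD deviation**: residual vectors for ASD scans are shifted by δ
  residual SDs (FA down, diffusivities up) and scaled by κ ≥ 1 — deviation
  applied where the analysis measures it, keeping δ and κ interpretable as
  effect sizes. δ = 0, κ = 1 is an exact null.
* **Phenotypes**: per-group means/SDs follow the study's demographic table
  (e.g. FSIQ 99.4 ± 17.7 ASD vs 118.2 ± 13.2 TDC). Within ASD, each
  variable mixes the standardized *latent* deviation magnitude (the
  Mahalanobis norm of the subject's shift-plus-intercept vector under the
  true covariance) with independent noise so the population correlation
  equals the configured link (FSIQ −0.28, PIQ −0.27, VIQ −0.21, SRS +0.12).
  Correlations computed on *measured* D_M are attenuated relative to these
  latent links, because subject-mean distances carry scan-level noise that
  the latent magnitude does not; the suite verifies the latent link
  recovery, not the attenuated one.

What the generator does **not** emulate: image acquisition and processing,
sedation effects, site/protocol drift beyond the coil flip, missing scans,
diagnosis uncertainty, or any real-data marginal distribution. Passing
tests therefore show that the *pipeline* behaves as specified under its own
assumptions — correct recovery, calibration and ordering — not that those
assumptions hold in any clinical dataset.

## Calibration results and a known miscalibration

Three properties anchor the suite (problem sizes chosen to keep the default
run in minutes: the replicate studies use an 8-feature spec, 2 ROIs × 4
parameters, at the full 421-scan design):

* Under the exact null, the pooled t-test on subject-mean D_M (ASD scored
  against the full TDC model, TDC leave-one-out) rejects at the nominal 5%
  over 200 replicate cohorts.
* The variance-ratio **F-test does not calibrate** under the same null: it
  rejects at roughly 13%. This is intrinsic, not an implementation defect —
  subject-mean distances are chi-like, correlated within subject through
  the shared random intercept, and averaged over 1–4 scans, so their
  distribution is skewed and heterogeneous-variance across subjects; the
  normal-theory F test is highly sensitive to exactly that. A
  pure-statistics simulation (subject-mean χ₈ distances with the study's
  scan-count mixture and a shared subject component, no fitting at all)
  already rejects at ~8.5%. The F statistics are still reported — they are
  the field's convention for "more variable" — but their null p-values
  should be read as anticonservative; a permutation reference would be the
  principled replacement and is listed under limitations.
* With a moderate distributed effect (δ = 0.3, κ = 1.5), the all-feature
  D_M distributions show smaller normalized Bhattacharyya overlap than
  every univariate standard-score distribution in ≥ 90% of replicates — the
  framework's central qualitative claim, and the reason to prefer the
  multivariate score.

## Numerical conventions and edge cases

* Distances are computed through the Cholesky factor of S (triangular
  solves); no matrix is ever explicitly inverted. Factorization-solve and
  explicit-inverse results agree to 1e-10 in tests.
* Bhattacharyya: zero pooled range (all values identical in both samples)
  returns 1 by convention, with a message. Disjoint supports return exactly
  0.
* Exceedance fractions use strict inequality; a value exactly at the
  threshold does not count.
* Cohort CSVs are written with shortest-round-trip decimals and read with
  base R's correctly-rounded parser, so write → read is the exact identity.
* The t-test df is n₁ + n₂ − 2 = 147 at the default design (the motivating
  study prints 141 without explanation; that choice is not replicated).
  Normalized Bhattacharyya coefficients are ≤ 1 by construction; the
  study's printed coefficients exceed 1 and its TDC mean distances are far
  below the √m scale, so neither magnitude is matched — the raw-count-scale
  coefficient is reported alongside for structural comparison only.
* An optional `loo = FALSE` mode scores controls in-sample; it exists for
  measuring the LOO optimism gap, not for analysis.

## Limitations

* Random intercepts only; no random slopes or non-Gaussian responses.
* The F comparison of variability is anticonservative for distance
  distributions (above); permutation or bootstrap references are future
  work.
* Shrinkage targets the diagonal only; structured targets (e.g. the
  Kronecker form the generator itself uses) could do better at m = 76.
* No decomposition of D_M into feature contributions (PCA-style
  attribution is out of scope).
* The generator's phenotype link is linear in latent deviation; real
  phenotype-brain relationships need not be.
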