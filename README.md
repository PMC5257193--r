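# mahanorm

Normative developmental trajectories and Mahalanobis deviation scores for
longitudinal regional white-matter microstructure.

## The problem

Diffusion-tensor imaging (DTI) studies of neurodevelopmental conditions such
as autism spectrum disorder (ASD) typically compare groups one region and one
parameter at a time. But microstructural alterations are often subtle,
distributed across many tracts, and heterogeneous across individuals — a
single-region z-score misses them. `mahanorm` implements a multivariate
normative-modelling alternative for accelerated longitudinal designs (each
subject contributes 1–4 scans at staggered ages):

1. **Normative trajectories.** For every (ROI, parameter) feature — by
   default 19 white-matter tracts × {FA, MD, AD, RD}, m = 76 — a reference
   growth curve is fitted on typically developing controls (TDC): a penalized
   cubic B-spline smooth of age with head-coil and motion (TMI) covariates
   and a per-subject random intercept, smoothing selected by REML.
2. **Deviation scoring.** Each scan yields a vector of marginal residuals
   x − μ(age, covariates) against the normative curves. With S the
   scan-level covariance of TDC residuals (diagonal-target shrinkage by
   default), the per-scan deviation is the Mahalanobis distance

   D_M = sqrt( (x − μ) S⁻¹ (x − μ)ᵀ ),

   averaged over a subject's time points into one representative value.
   Controls are scored **leave-one-out**: each TDC subject's scans are held
   out, all curves and S are re-estimated, and the subject is scored against
   models that never saw them.
3. **Distribution analysis.** Group comparisons of the subject-level D_M
   distributions (pooled t, variance-ratio F, Bhattacharyya overlap,
   exceedance fractions above the TDC mean and mean + 2 SD), univariate
   standard scores (residual / residual SD) for comparison, and Pearson
   correlations of D_M with phenotypes (FSIQ, PIQ, VIQ, SRS).

Because the motivating study's clinical cohort is not public, the package
ships a **synthetic-cohort generator** that emulates the study design of
record (92 ASD + 57 TDC males, 421 scans, baseline ages 3.1–36.8 y, mean
inter-scan interval 2.6 y), exponential-approach trajectories, correlated
residuals, covariate effects, a configurable ASD deviation (shift δ in
residual-SD units, variance inflation κ) and phenotypes linked to true
deviation magnitude — with full ground truth retained for recovery tests.

## Worked example

```r
library(mahanorm)

cfg <- cohort_config(asd_shift = 0.8, asd_scale = 2)  # full 76-feature set
sim <- generate_cohort(cfg, seed = 7)
sim
#> Synthetic longitudinal cohort (seed 7)
#>   149 subjects, 421 scans, 76 features

pp <- run_pipeline(sim$cohort, sim$phenotypes,
                   presets = c("ALL", "FA", "MD", "FA_MD"))
pp
#> Normative-deviation pipeline (4 presets, TDC scoring: leave-one-out)
#>
#>  preset  m t_stat t_df f_stat bc_normalized frac_above_mean
#>     ALL 76  47.72  147  4.396       0.00000               1
#>      FA 19  24.21  147  1.860       0.09082               1
#>      MD 19  26.92  147  2.266       0.01381               1
#>   FA_MD 38  34.73  147  3.067       0.00000               1
#>  frac_above_mean_plus_2sd
#>                    1.0000
#>                    0.9783
#>                    1.0000
#>                    1.0000
```

Reading the output: under a strong configured deviation (δ = 0.8, κ = 2)
the ASD distance distribution separates completely from the TDC
distribution when all 76 features are combined — the Bhattacharyya
coefficient of the ALL preset is exactly 0 (disjoint histograms) and every
ASD subject lies above the TDC mean — while each single-parameter preset
separates less (larger overlap, smaller t). That ordering — the multivariate
deviation discriminates better than any univariate restriction — is the
package's central reproducible claim, tested over replicate cohorts in the
acceptance suite. Phenotype correlations computed on *measured* D_M are
attenuated relative to the configured latent link (the generator calibrates
FSIQ against true deviation magnitude at r = −0.28; see the vignette).

Per-feature fits are inspectable the broom way: `glance(fit)` for smoothing
parameter / effective degrees of freedom / variance components,
`tidy(result)` for subject-level scores, and `autoplot()` for trajectory and
distribution figures.

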