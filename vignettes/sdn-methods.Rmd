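---
title: "Mapping synchronized degeneration networks from longitudinal volumetric maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping synchronized degeneration networks from longitudinal volumetric maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdnmap)
```

## The problem

Neurodegenerative disease is increasingly understood as a network
phenomenon: pathology appears first in *epicenters* — regions that are
selectively vulnerable — and appears to progress along the large-scale
brain networks those regions belong to. A longitudinal way to probe this
is the **synchronized degeneration network (SDN)**: the set of voxels
whose *annual atrophy rates* covary, across subjects, with the atrophy
rate of a seed region. If the network hypothesis holds, an SDN seeded at a
disease epicenter should predict where atrophy concentrates in patients
and how fast cognition declines.

`sdnmap` implements that analysis chain for serial volumetric change maps
(Jacobian-determinant-like maps in a common space, values near 1, > 1
expansion, < 1 contraction):

1. **Rate maps** — per subject, the OLS slope of map value on acquisition
   time at every voxel (units: fractional volume change per year), then
   isotropic Gaussian smoothing (8 mm FWHM by default).
2. **Group statistics** — mass-univariate ANCOVA across four groups
   (HC, stable MCI, progressive MCI, AD) with age, sex, education and
   total intracranial volume as nuisance covariates; one-sample t-tests
   per group for degeneration patterns; t maps converted to z.
3. **Cluster-extent FWE correction** — residual smoothness estimated from
   first differences, then a Monte-Carlo simulation of smoothness-matched
   Gaussian noise determines the minimum cluster extent at voxel
   p < 0.005, familywise alpha 0.05.
4. **Epicenters and SDNs** — 6-mm sphere seeds at the peak voxels of the
   surviving clusters of the progressive-vs-stable MCI contrast; per seed,
   a GLM of voxel rate on the seed's mean rate (plus covariates) in the
   control group yields the SDN z map, binarized at the same cluster-FWE
   criterion.
5. **Spatial similarity** — Pearson correlation between unthresholded SDN
   and group maps, judged against a null of 1,000 Gaussian noise maps
   smoothed to the SDN map's estimated smoothness.
6. **Network preference (GOF)** — goodness of fit = mean z inside the
   binarized network minus mean z outside, also profiled over fixed-size
   networks (top 1–10 % of voxels).
7. **Cognitive association** — partial Spearman correlation between the
   mean SDN atrophy rate and per-subject cognitive slopes, Bonferroni
   corrected over six domain tests with the global screening test (MMSE)
   judged separately at the uncorrected level (0.05/6 ≈ 0.008).

Because real cohorts of this kind are rarely shareable, the package ships
a synthetic cohort generator with planted ground truth, and the test suite
treats recovery of that truth as the primary evidence that the chain
works.

## The generative model

For subject $i$ and voxel $v$ the true annual rate is

$$ r_{v,i} \;=\; \beta_{0,v} \;+\; \sum_k \lambda_{k,v}\, f_{k,i}
   \;+\; \sum_c \gamma_{c,v}\, z_{c,i} \;+\; \eta_{v,i}, $$

and the observed map at time $t$ is $1 + r_{v,i}\,t + \varepsilon_{v,t}$
with spatially smooth visit noise $\varepsilon$. The pieces:

* $f_{k,i} \sim N(\mu_{g(i),k}, \sigma_f^2)$ — one latent atrophy factor
  per planted network, with group-graded means (HC mildest, AD most
  negative). Multiple epicenters get independent factors, which keeps
  seed-based recovery well-posed.
* $\lambda_{k,v}$ — network loadings: a radial Gaussian profile
  (scale 3 voxels, optional flat core) truncated to zero beyond radius
  3.5 voxels. The peaked profile keeps the peak of any group contrast
  close to the planted epicenter, and the hard truncation makes "the true
  network" a well-defined voxel set for Dice scoring whose edge voxels
  still carry about half the peak loading — a network no method could
  fully recover would be a vacuous truth.
* $z_{c,i}$ — nuisance covariates standardized inside the generator with
  fixed location/scale (age 76 ± 6 y, education 12 ± 4 y, TIV
  1.46 × 10⁶ ± 1.3 × 10⁵ mm³, sex ± 0.5), so `covariate_effects` are
  per-SD rate slopes.
* $\eta_{v,i}$ — a per-subject spatially smooth rate-heterogeneity field
  (default SD 0.0065/yr). This term is not strictly needed to plant a
  network, but without it out-of-network voxels would have essentially
  zero between-subject rate variance and one-sample t statistics would be
  degenerate (unbounded everywhere). Individual variation in aging rate is
  also simply a feature of real cohorts.
* Cognitive decline: each test's true slope is
  $b_t \cdot \bar r_i + e$, where $\bar r_i$ is the subject's mean rate
  over the coupled network voxels; observed scores add per-visit noise.
  Trajectories are linear throughout because every downstream statistic
  uses only the fitted slope — linear generation makes ground-truth slopes
  exact and parameter-recovery tests closed-form.

Defaults mirror a memory-clinic style study: group sizes 33/25/12/23,
three nominal annual visits with an 18 % two-visit attrition fraction
(exactly 1.0-year spacing by default, jitter available), a 32³ grid of
3-mm voxels, two planted networks, visit noise SD 0.008 at 6-mm
smoothness, latent factor SD 0.008 with group means −0.004 / −0.008 /
−0.028 / −0.036 per year. The group-mean spread is deliberately wider
than the within-group SD for the progressive-vs-stable MCI pair — and the
effect sizes overall are calibrated so that the preset satisfies its own
recovery contract (epicenters localized, networks recoverable at
Dice ≥ 0.5, GOF graded with severity in the large majority of seeds) at
these pinned, small group sizes: with only 12 progressive subjects, a
weaker contrast would rarely survive cluster correction, and a planted
truth the pipeline cannot in principle recover would test nothing. Two
subtleties drove the calibration: the progressive-MCI group's low
residual degrees of freedom (7) cap its one-sample z values, so pushing
effects *too* high compresses that group's GOF below the stable-MCI
group's and breaks the severity ordering; and a flat-topped loading
profile lets the contrast peak wander off the epicenter, so the profile
is peaked.

What the generator does **not** emulate: registration/segmentation error,
partial-volume effects at tissue borders, non-brain topology (the mask is
the whole grid), temporal autocorrelation of visit noise (the slope model
assumes independent residuals), non-linear trajectories, and spatially
realistic anatomy. Passing tests therefore demonstrate the *statistical
machinery* — calibration, recovery, ordering — not robustness to
registration artifacts.

## Numerical and design choices

* **Smoothing** is separable discrete Gaussian convolution with
  zero-padding and no boundary renormalization, kernel truncated at 4σ.
  Constants are preserved in the interior only; masks are applied at the
  statistics stage, never baked into the smoother. Smoothed noise fields
  are rescaled by the exact kernel factor $\prod_a \sqrt{\sum k_a^2}$ so
  the *interior* marginal SD is the requested one.
* **Mask threshold** is strict (mean > 0.2): a mean of exactly 0.2 is
  excluded. The direction at equality is a convention; it is configurable.
* **Smoothness estimation** uses the classical first-difference ratio
  $\mathrm{FWHM} = \Delta\sqrt{-2\ln 2 / \ln(1 - \mathrm{var}\Delta /
  (2\,\mathrm{var}))}$ per axis, averaged over maps, geometric mean across
  axes, floored at half a voxel. The estimator is accurate for kernels of
  roughly 2–4 voxels (the regime the pipeline operates in after 8-mm
  smoothing); for nearly unsmoothed data the discrete lattice makes it
  bias low, which is why the acceptance checks target the 2–4 voxel range.
* **Cluster inference** thresholds two-sided (|z| above the 1 − p/2
  quantile) and clusters the combined exceedance set under
  18-connectivity by default (6 and 26 available). The Monte-Carlo null is
  Gaussian, not t, because thresholds are applied to z-converted maps. The
  minimum extent is the smallest k with an empirical max-cluster
  exceedance probability ≤ α. A widely used printed value for this kind of
  analysis (e.g. 513 voxels at 1.5-mm voxels and whole-brain masks) is
  data-dependent and is *not* hard-coded anywhere; each run simulates its
  own extent.
* **Group coding** is cell-means (one indicator per group, no intercept),
  so contrasts are direct group-mean differences; covariates are
  mean-centered, making one-sample intercept tests evaluate the mean rate
  at covariate means. Zero-residual-variance voxels get z clamped to ±38
  with a warning.
* **Ties**: cluster peaks and top-percent cut ties resolve by smallest
  linear scan-order index — deterministic and documented.
* **SDN binarization** keeps the positive-coupling direction by default
  ("synchronized degeneration" is positive covariance of rates); a
  two-sided option exists. By default the extent threshold simulated for
  the group contrast is reused for SDN binarization (the residual
  smoothness is near-identical since both inherit the same smoothed
  acquisition noise); per-seed re-simulation is a switch away.
* **Permutation similarity** replaces the SDN side with
  smoothness-matched noise (the target map stays fixed), uses two-sided
  exceedance on |r|, and the add-one estimator
  $(1 + \#\{|r_0| \ge |r|\})/(1 + N)$, so p is never exactly 0 and can
  reach 1 — matching how such extremes are conventionally reported.
* **Partial Spearman** is rank-then-residualize: all variables are
  rank-transformed, ranked x and y are residualized on ranked covariates
  by OLS, and the residuals correlated, with a t approximation on
  $n - 2 - k$ degrees of freedom. This is the standard construction among
  the two in common use; it is invariant to monotone transforms of x and
  y. Correlations pool all subjects (no group stratification by default).
* **Cognitive slopes** are per-subject OLS fits, not annualized
  differences; with two time points the two coincide.
* **Seeding**: every stochastic stage draws from a child seed derived
  deterministically from one master seed, recorded in the run manifest;
  reruns are bitwise identical.

## Tuned presets and what the tests show

`cohort_preset("null")` removes all signal (zero loadings, zero baseline,
unsmoothed noise) and is used for calibration: the voxel-level
false-positive fraction at p < 0.005 sits inside the 3-SE binomial band,
the cluster-FWE rate over 200 null datasets falls in [0.02, 0.10] at
nominal 0.05, and permutation similarity p-values are uniform under the
null (KS at α = 0.01).

`cohort_preset("association")` plants one severity-graded coupled network
and one uncoupled decoy with group-independent atrophy. The residual SD of
the cognitive slope is solved analytically so the model-implied Spearman
correlation between network rate and slope is 0.40 (via the bivariate
normal identity ρ = 2 sin(πρₛ/6), including the exact variance of the
averaged smooth heterogeneity field). At n = 93 and the Bonferroni
threshold 0.05/6, detection power for a 0.4 rank correlation is about
0.9, which the test suite checks as ≥ 80 % of seeds significant, with the
decoy staying non-significant in ≥ 90 %.

Problem sizes used by the default test and acceptance runs — 32³ grids,
1,000-draw cluster simulations, 200 calibration replicates, 20 recovery
seeds, 40 association seeds — were chosen as the smallest sizes at which
the binomial/Monte-Carlo error of each check is comfortably below the
margin being asserted.

## Known limitations

* Plain OLS is used for every voxel-wise model; no variance smoothing,
  robust fitting, or permutation-based voxel inference.
* The Monte-Carlo null is Gaussian with a single FWHM per axis; heavier
  tailed or spatially non-stationary autocorrelation (which motivates ACF
  extensions of the classical cluster simulators) is out of scope.
  Relatedly, z maps converted from very low-df t statistics are rougher
  than a Gaussian field of the residuals' FWHM, so cluster thresholds
  become conservative for tiny groups (empirically visible below about
  n = 20); at the group sizes the pipeline targets the familywise error
  calibrates within the expected band.
* No surface-based or variogram-matched ("spin test") nulls for spatial
  similarity.
* Anatomical labeling of network regions is descriptive work outside the
  package.
* The pipeline begins at registered change maps; registration,
  segmentation and template construction are upstream and unmodeled.
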