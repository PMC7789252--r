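---
title: "Kernel machine models for prenatal metal mixtures and child blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel machine models for prenatal metal mixtures and child blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Prenatal exposure to metals rarely happens one element at a time.
Urinary panels measure a correlated mixture — here eight elements
(As, Cd, Co, Mg, Mo, Pb, Sb, Se) measured in maternal pregnancy urine —
and the scientific questions are mixture questions: which components
matter, are the exposure-response relationships nonlinear (essential
elements are expected to be protective at low and harmful at high
doses), and do components act synergistically? When the outcome is a
child's blood pressure (BP) measured repeatedly across childhood, there
is a further axis: does the mixture shift the *level* of BP, its *rate
of change* with age, or both?

This package implements the two Bayesian kernel machine models that
address these questions, the preprocessing that produces their
standardised exposure matrix, the outcome classifiers for elevated BP,
the posterior summaries used for reporting, confirmatory single-metal
penalised-spline fits, and a calibrated synthetic cohort generator that
makes the whole pipeline testable without access to any cohort data.

## The longitudinal model

`bvckmr()` fits, by Gibbs sampling,

$$y_{ij} = \gamma_1 + \gamma_2\,a_{ij} + h_1(z_i) + h_2(z_i)\,a_{ij}
  + x_{ij}^{\mathsf T}\beta + b_i + \epsilon_{ij},$$

where $y_{ij}$ is the systolic or diastolic BP of child $i$ at visit
$j$ (mmHg), $a_{ij} = \mathrm{age}_{ij} - 4$ years, $z_i$ is the
subject's standardised exposure profile, $b_i \sim N(0, \sigma_b^2)$ a
subject random intercept and $\epsilon_{ij} \sim N(0, \sigma_e^2)$.
Centring age at 4 years makes $h_1$ the mixture surface for baseline
(age-4) BP and $h_2$ the surface modifying the per-year change
(mmHg/yr); $\gamma_1$ (mmHg) and $\gamma_2$ (mmHg/yr) are the
population intercept and slope.

$h_1$ and $h_2$ carry independent Gaussian-process priors
$h \sim N(0, \tau^2 K)$ with the component-weighted Gaussian kernel

$$K_{ab} = \exp\Big\{-\sum_m r_m (z_{am} - z_{bm})^2\Big\},$$

so each surface has its own scale $\tau^2$ and its own nonnegative
weight vector $r$. A weight $r_m = 0$ removes metal $m$ from that
surface entirely; spike-and-slab priors on the $r_m$ (inclusion
probability 0.5, uniform$(0, 100)$ slab) perform Bayesian variable
selection per surface.

### Binary outcomes

`bkmr_probit()` fits the single-time-point analogue
$P(y_i = 1) = \Phi\{h(z_i) + x_i^{\mathsf T}\beta\}$ for elevated BP at
the final visit, using truncated-normal latent-variable augmentation so
that all updates reduce to the Gaussian machinery above with unit
residual variance. Selection is hierarchical: a Bernoulli(0.5)
indicator per element *group* (toxic As/Cd/Pb/Sb versus essential
Co/Mg/Mo/Se), and — when a group is active — exactly one
uniformly-chosen representative component within it. Group posterior
inclusion probabilities (PIPs) and within-group conditional PIPs
(which sum to one over each active group) rank the mixture components
(`compute_pips()`).

## Sampler design

Three design choices matter for getting usable chains at realistic
lengths; all three are standard devices, combined:

1. **Collapsed surface updates.** The random intercept $b_i$ and the
   subject-level surface values $h_1(z_i)$ are both subject-level
   intercepts, separated only by their priors. Each surface is
   therefore drawn from its Gaussian full conditional with $b$
   marginalised into the noise (per-subject pseudo-observations
   $u_i$ with variance $v_i = \sigma_e^2/n_i + \sigma_b^2$ for $h_1$,
   and the age-weighted analogue for $h_2$), and $b$ is redrawn
   afterwards.

2. **Marginal-likelihood Metropolis moves for the kernel.** The
   weights $r$ and scale $\tau^2$ are updated against
   $N(u;\,0,\ \tau^2 K(r) + \mathrm{diag}(v) + V_\theta J)$, i.e. with
   the surface itself integrated out. Moves that condition on a drawn
   surface cannot leave the empty model in practice; the marginal form
   sees the data directly. The $V_\theta J$ term ($J$ the all-ones
   matrix, $V_\theta$ the fixed-effect prior variance) additionally
   integrates out the one coefficient that is confounded with the
   surface's free level — the intercept for $h_1$, the age slope for
   $h_2$, the probit intercept for $h$ — which prevents the
   level-trading cycle in which $\tau^2$ inflates to absorb the
   intercept. That coefficient is then redrawn from its
   surface-marginal conditional before the surface itself is drawn.

3. **A genuinely empty null model.** With no active component the
   Gaussian kernel degenerates to the all-ones matrix, a pure free
   level. The sampler instead treats "no components selected" as
   $h \equiv 0$ with no $\tau^2$, and moves between the empty and
   non-empty models by reversible-jump birth/death steps that propose
   $(r_m, \tau^2)$ jointly, the $\tau^2$ proposal log-normal around a
   data-scaled pilot value. Within the non-empty model, weights move by
   birth/death (exponential proposal, rate 4) and log-scale random
   walks whose step size is adapted to a 20–40% acceptance rate during
   burn-in and frozen afterwards.

Everything else is conjugate: fixed effects from a normal block
($N(0, 10^4)$ priors), $b_i$ from normals, $\sigma_e^2$ and
$\sigma_b^2$ from inverse-gamma$(0.001, 0.001)$ conditionals; $\tau^2$
moves by marginal Metropolis under the same inverse-gamma prior. The
compiled core (RcppArmadillo) draws all randomness through R's RNG, so
`set.seed()` gives bit-identical chains.

The production schedule of the motivating analysis — 100,000
iterations, first half burn-in, thinning by 10 for the binary model —
is available by the `niter`/`burnin`/`thin` arguments
(`mcmc_retained(100000, 50000, 10)` = 5,000 retained draws).
Simulation work in the test-suite uses 1,200–5,000 iterations, sizes at
which the recovery and coverage diagnostics below are already stable.

## Posterior summaries

* `iqr_contrast()` — the relative-importance measure: the change in a
  surface when one metal moves from its 25th to its 75th observed
  percentile, all others held at their medians; posterior mean and
  equal-tailed 95% credible interval, flagged significant when the
  interval excludes zero.
* `exposure_response()` — a curve over an equally spaced grid spanning
  the metal's observed 1st–99th percentile (50 points by default),
  other metals at medians. Each retained draw is extended to the grid
  by GP conditioning under *that draw's* kernel weights (draws sharing
  a weight vector share one factorisation), which propagates
  hyperparameter uncertainty; a plug-in mode conditioning the
  posterior-mean surface on posterior-mean hyperparameters is offered
  for speed.
* `bivariate_surface()` — the first metal's curve at chosen quantiles
  of a second metal (25th/75th for longitudinal fits, 10th/50th/90th
  for binary fits): parallel curves indicate additivity.
  `cross_difference()` is the corresponding scalar finite-difference
  interaction measure.
* `find_inflection()` — the interior minimum of the posterior-mean
  curve, located by the sign change of successive differences and
  reported in original concentration units through the stored
  transform; monotone curves return none. The estimator's resolution
  is one grid step, and for shallow minima its sampling variability
  spans several grid steps at $n = 176$ — single-cohort inflection
  estimates should be read with that in mind.

## Preprocessing

The pipeline order is fixed: below-LOD policy (default: retain the
instrument value, keep the flag; LOD/$\sqrt2$ substitution available),
specific-gravity dilution adjustment
$c \times (\mathrm{ref} - 1)/(\mathrm{sg} - 1)$ with reference 1.020,
outlier exclusion, then log2 transform, centring and scaling (sample
SD, $n-1$). The mean $\pm$ 4 SD screen is applied on the log2
SG-adjusted scale — the scale all downstream modelling uses — and
exclusion is listwise; screening on the raw scale is available by
argument. The transform record (per-metal centre, scale, reference SG)
makes every standardised quantity convertible back to
micrograms per litre (milligrams per litre for Mg).

## Outcome definitions

Visit BP is the arithmetic mean of at least three readings
(`average_readings()` warns below three). Elevated BP at the final
visit is classified two ways: the static school-age cutoffs — systolic
$\ge 110$ mmHg (inclusive) and/or diastolic $> 70$ mmHg (strict),
exactly as printed — and percentile cutoffs (systolic or diastolic at
or above the 90th percentile for sex, age and height). No normative
table is embedded: `classify_elevated_percentile()` takes any reference
in a documented CSV schema, interpolating linearly in age and height
percentile, with height percentiles derived from a user-supplied growth
reference. A small synthetic toy reference ships for tests and
examples; its thresholds are calibrated so that, on the default
synthetic cohort, the static definition yields the higher prevalence —
the direction observed with the real AAP tables — but its absolute
prevalences carry no normative meaning.

## The synthetic cohort generator

`truth_spec()`/`simulate_cohort()` define the study conditions every
validation runs under.

**Exposures.** The generator draws *dilution-corrected* concentrations
from a multivariate log-normal — per-metal geometric means and log-SDs
calibrated to the published cohort summaries (e.g. Mo GM 58.15 μg/L,
log-SD fitted to the p10–p90 spread), correlation matrix with a weak
positive default (0.15) and the one printed pairwise value, Cd–Pb
0.45 — then draws specific gravity from a truncated normal (mean
1.020, SD 0.006, bounds 1.001–1.040) and derives the raw spot-sample
value as $\mathrm{adj} \times (\mathrm{sg}-1)/(\mathrm{ref}-1)$. This
is deliberate: dilution is a multiplicative nuisance shared by all
metals in a spot sample, and SG adjustment exists to remove it. Under
this generative model the adjustment at preprocessing recovers the
configured mixture distribution exactly, so the calibration anchors are
checked on the dilution-corrected scale — the same scale on which the
published correlations are computed. The alternative (independent SG,
calibration on the raw scale) cannot match raw and adjusted summaries
simultaneously and distorts the correlation structure the models
consume.

**Covariates and trajectories.** Maternal age, 3-level education, BMI
and smoking, child sex, exact visit ages, sex- and age-dependent
heights, and ETS flags follow the published cohort's means, SDs and
frequencies. BP is generated from the model equation itself with
$\gamma_1, \gamma_2$ set so the mean trajectory rises like the
published visit means (SBP ≈ 90.6 → 94.0 → 105.8 mmHg), covariate
effects defined on centred covariates so the calibration is not
disturbed, and variance components ($\sigma_b^2 = \sigma_e^2 = 25$ for
SBP, 15/15 for DBP) reproducing the published SDs of roughly 7.5–9.5
mmHg with within-subject correlation 0.5.

**Effect sizes.** The default $h_1$ is J-shaped in Mo — a quadratic in
standardised log2 Mo with interior minimum at 60 μg/L, centred to mean
zero — plus a Mo×Pb product term; $h_2$ is linear in Mo and Co with the
reported per-year magnitudes. Curvature (2.5 mmHg/SD²) and interaction
(1.5 mmHg/SD²) were chosen once, as the same order of magnitude as the
published interquartile contrasts (0.7–1.3 mmHg) while large enough
that surface-recovery tests at $n = 176$ are informative; they were not
revisited afterwards. The interaction-detection validation uses its own
purpose-built pair of truths (identical cohorts with and without a
3 mmHg/SD² product term) sized by a power computation against the
selection threshold below.

**What the generator does not emulate:** assay batch effects and
measurement error, missing data, cohort-selection processes, and any
real-data deviation from log-normality or from the assumed trajectory
linearity in age. Passing recovery tests on this generator shows the
estimator is correct under its own assumptions; it does not certify
behaviour under model misspecification.

## Numerical choices

* Kernel factorisations use jitter escalation: start at
  $10^{-8}\,\mathrm{tr}(K)/n$, multiply by 10 at most three times, then
  fail loudly with a condition diagnostic.
* Surface prediction at new points uses the conditional mean
  $K_* K^{-1} h$ per retained draw; identical weight vectors are
  batched through one factorisation.
* The standardisation example column $\{1, 2, 4\}$ maps to
  $\{-1, 0, 1\}$: the sample-SD ($n-1$) convention is used throughout
  and recorded in the transform metadata.
* Ties and degenerate inputs: constant metal columns abort
  standardisation; a zero-SD outlier screen excludes nothing; subjects
  carrying no information about $h_2$ (all visits at the centring age)
  receive an effectively infinite pseudo-observation variance.

## Selection behaviour and known limitations

With a diffuse uniform$(0,100)$ slab, marginal-likelihood selection
pays a Lindley-type penalty of several nats for activating a component.
Two practical consequences, both visible in the test-suite: under null
exposures the group PIPs concentrate near zero (not near the 0.5
prior) — selection is conservative, which also makes the null-coverage
checks comfortable; and weak real effects (roughly below 2 mmHg per SD
at $n = 176$, residual scale ~33 mmHg²) tend to stay unselected. The
indicator chains also mix slowly compared with everything else in the
model — the motivation for the production-scale 100,000-iteration
schedule — so PIP estimates from short exploratory chains carry
substantial Monte-Carlo error.

Because every visit lies at or above the age-4 baseline, the baseline
surface $h_1$ is a mild extrapolation: estimation error in $h_2$ leaks
into $h_1$ with weight roughly the mean centred age (~3 years). In
simulation this shows up as a small systematic tilt of the recovered
baseline curve — enough to displace the location of a shallow J-curve
minimum by a few tenths of a standardised unit even when the surface
itself is recovered with correlation above 0.9. Inflection-point
locations should therefore be reported with their imprecision, not as
sharp thresholds.

The percentile classifier is only as good as the reference tables it is
given; the shipped toy reference is synthetic. The GAM/GAMM
confirmatory fits (`fit_metal_gamm()`, `fit_metal_interaction()`,
P-splines with GCV via mgcv) report effective degrees of freedom,
fitted curves and interaction variance shares, but approximate
smooth-term p-values are deliberately out of scope.
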