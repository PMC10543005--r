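---
title: "Methods: twin-cohort placebo analysis with heteroskedastic mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-cohort placebo analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placebotwin)
```

## The scientific problem

Placebo analgesia experiments in twin cohorts combine three statistical
difficulties at once: a within-participant factorial design (stimulus level x
treatment condition, repeated over trials and runs), family clustering (twins
are not independent observations), and zygosity heteroskedasticity
(dizygotic co-twins are expected to differ more from each other than
monozygotic co-twins, because they share less genetic variance).  Treating
participants as independent inflates degrees of freedom; treating MZ and DZ
families as equally variable biases the fit toward the more numerous or more
variable group.  On the neural side, the quantity of interest is rarely a
single voxel: multivariate signature scores (the dot product of a contrast
map with a fixed weight map) and region-of-interest averages reduce each
participant-by-condition contrast image to a scalar that enters the same
mixed model as the behavioral ratings.

`placebotwin` implements that full path — synthetic cohort and trial
generation with known ground truth, a minimal first-level GLM, signature and
ROI scoring, quality-control exclusions, the zygosity-heteroskedastic twin
mixed model with Satterthwaite inference, Jeffreys-Zellner-Siow (JZS) Bayes
factors for nested fixed effects, and individual-difference correlation
models — so every stage can be exercised and validated end to end without
access to any participant data.

## The twin mixed model

For one modality, with stimulus level coded $-0.5, 0, +0.5$ (low, medium,
high) and condition coded $-0.5$ (control) / $+0.5$ (placebo), the response
model is

$$
y_{fit} = \beta_0 + \beta_L L_{it} + \beta_P P_{it} (+\, \beta_{LP} L_{it} P_{it})
 + b_f^\top z_{it} + u_i^\top z_{it} + \varepsilon_{fit},
$$

where $z_{it} = (1, L_{it}, P_{it})$, $b_f \sim N(0, \Sigma_{\text{fam}})$ is
shared by both members of family $f$, and the individual deviation $u_i$ has
zygosity-specific covariance: $u_i \sim N(0, \Sigma_{\text{MZ}})$ for MZ
twins and $N(0, \Sigma_{\text{DZ}})$ for DZ twins.  Implementation-wise the
individual random effects are duplicated into an MZ copy and a DZ copy with
the off-zygosity copy zeroed, which makes the random-effect covariance block
diagonal by zygosity — the repeated-measures generalization of a
heteroskedastic twin error model.  Singletons receive only the family draw;
their individual effect is not separable from the family effect in a
one-member family, so both the generator and the fitted model set it to
zero.

### Estimation

`reml_fit()` maximizes the restricted likelihood over a log-Cholesky
parameterization of each covariance block (every iterate is positive
definite by construction) plus a log residual variance, using a
quasi-Newton optimizer with an analytic gradient and deterministic restarts.
Families are independent, so the likelihood factors over family blocks; the
per-block Woodbury identity reduces each evaluation to a handful of
$q \times q$ solves with $q \le 9$.  Families with bit-identical design
cross-products (after canonical row ordering) are pooled, so a balanced
simulated cohort costs three distinct design groups per evaluation
regardless of the number of families — this is what makes the
1000-replicate calibration suite feasible on one CPU.

Numerical choices that matter:

* **Convergence**: parameter/objective relative tolerance `1e-12`
  (`reml_control(rel_tol=)`), three optimizer starts (one nominal, two
  deterministic perturbations).  Zero-variance solutions are legal boundary
  fits: they are flagged (`convergence$boundary`), never errors.
* **Box constraints**: log-SDs are floored at $-20$ and the log residual
  variance at $-40$ on the unconstrained scale.  Without a floor, boundary
  fits drift toward $-\infty$ where the precision matrices overflow.
* **Satterthwaite degrees of freedom**: for a contrast $c$,
  $\mathrm{df} = 2 f^2 / \widehat{\mathrm{Var}}(f)$ with
  $f(\theta) = c^\top (X^\top V^{-1} X)^{-1} c$, the variance obtained by the
  delta method from the inverse observed REML information.  The Hessian is
  the central-difference Jacobian of the analytic gradient with step `1e-4`;
  a step of `1e-5` was tried first and is roundoff-dominated (the Welch
  two-group oracle then agrees only to ~2e-4 rather than ~1e-6), so the
  larger step is the package's choice.  Flat directions of the information
  matrix — which arise exactly at variance boundaries and carry no
  information about the contrast variance — are removed by a positive-part
  pseudo-inverse.
* The protocol fits the interaction model first and refits without the
  interaction when it is non-significant at $\alpha = .05$
  (`interaction_protocol()`); every reported row is tagged with its source
  model.

## Bayes factors

`bf_fixed_effect()` compares the full model (fixed mains, optionally the
interaction, plus family and zygosity-split participant random *intercepts*
— no random slopes) against the same model minus the effect of interest.
The construction is JZS: the standardized outcome, a Cauchy prior with scale
`rscale` (default 1) on each standardized fixed effect, obtained as a normal
prior with variance $g\sigma^2$ and $g \sim r^2 \cdot
\text{inv-}\chi^2_1$; random-effect groups get the same construction with a
fixed nuisance scale of 1.  Conditional on the $g$ vector the marginal
likelihood is a closed-form Gaussian integral (flat intercept and Jeffreys
error-variance prior integrated analytically); the $g$ integral is done by
importance-weighted Monte Carlo.

The proposal is *not* the prior: with several random-effect groups the
conditional marginal concentrates sharply and prior draws produce a
degenerate weight distribution (effective sample sizes below 1% were
observed at desk scale).  Instead the sampler locates the mode of the
integrand in $\log g$ space, measures its diagonal curvature, and proposes
from an independent multivariate $t_4$ centered there with inflated scale.
Weights are integrand over proposal; the reported `proportional_error`
combines the relative Monte Carlo standard errors of the two marginal
likelihoods in quadrature, and an effective sample size below 5% of `n_mc`
is an error rather than a silent degradation.

Correctness is anchored in reductions with independent oracles: the
intercept-only marginal has a closed form (checked against direct
quadrature over $\sigma^2$), and the one-sample reduction must match the
classical one-dimensional JZS $t$-test integral at $t \in \{0,1,2,4\}$,
$n \in \{20,50\}$ within three combined Monte Carlo standard errors.

The printed prior-scale list for the robustness scan contains an apparent
duplication ("$\sqrt2/2, 1, 1, \sqrt2$"); the implemented grid is
$\{\sqrt2/2, 1, \sqrt2\}$ crossed with interaction absent/present (six
cells), with a qualitative flag marking whether all cells fall on the same
side of $1/3$ or $3$.  Evidence labels use the conventional bands at 3, 10,
30, 100 and their reciprocals; the paper-style odds string rounds the
(reciprocal) Bayes factor to integer odds.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to tests.

* **Cohort**: 142 MZ individuals, 160 DZ individuals, 93 singletons (395
  participants, 244 families).
* **Design**: 32 trials in 4 runs ordered control-placebo-placebo-control;
  8 trials per run, 4 thermal and 4 mechanical in shuffled order; three
  stimulus levels per modality.  Within each modality-by-condition cell the
  level multiset is 3 low / 2 medium / 3 high, so the centered level codes
  sum to zero exactly.
* **Effects** (z scale, defaults): thermal intensity 0.409 and placebo
  $-0.359$; mechanical 0.202 and $-0.244$; interactions 0.
* **Variance components** (defaults, not stated by any source and chosen
  once as field-plausible): family SDs $(0.5, 0.2, 0.2)$ for intercept and
  the two slopes; individual SDs $(0.40, 0.15, 0.15)$ for MZ and
  $(0.60, 0.25, 0.25)$ for DZ (DZ more variable within family); residual SD
  0.7.  These put roughly half of the non-residual variance at the family
  level and give within-pair correlations of participant means near 0.6
  (MZ) and 0.4 (DZ).
* **Ratings**: outcomes are generated on the z scale and mapped affinely
  into the gLMS $[0,1]$ range ($0.15 + 0.07z$, clipped; the clipped
  fraction is recorded).  The gLMS response distribution is not known, so
  this map is a stand-in, not an inference about any study.
  Unpleasantness is intensity plus $N(0, 0.48^2)$ noise, which yields a
  within-participant intensity-unpleasantness correlation near 0.9.
* **Reaction times**: log-normal around 1.1 s, truncated into the valid
  window; a configurable fraction is planted outside $[0.02, 5.01]$ s for
  exclusion-rule testing.
* **RNG**: one root seed; child streams per family, per participant, and
  per participant-run are derived by a documented integer-hash splitting
  rule (`child_seed()`), so tables and volumes are bit-reproducible and
  subsets can be regenerated independently.
* **Volumes**: synthetic signatures are disjoint all-positive or
  all-negative cuboid subregions (default 2 positive / 6 negative,
  mirroring the pre-registered subregion split); contrast maps plant a
  target score as `weights * target / ||w||^2` plus white noise so that the
  masked dot product recovers the target in expectation.

What the generator does **not** emulate: spatial autocorrelation and
physiological noise in volumes, raw BOLD time series (the GLM module builds
its own small fixtures), rating-scale use heterogeneity beyond the affine
map, conditioning-phase dynamics, and any real signature weights.  A green
simulation test therefore establishes the correctness of the estimators
under the stated generative model, not the reproduction of any empirical
dataset.

## First-level GLM choices

The GLM module is intentionally minimal: double-gamma HRF in the SPM
convention (peak 6, undershoot 16, ratio 1/6, 32 s support, unit peak),
boxcars convolved on a 16x oversampled grid; a cosine drift basis with
$K = \lfloor 2T/\text{cutoff} \rfloor$ columns; censoring of the first
eight frames plus spike frames via per-frame indicator columns (numerically
identical to row deletion, verified by a test).  The acquisition-derived
defaults are TR 0.46 s and 550 volumes per run.  A printed "180 Hz
high pass" is physically impossible at this TR and is read as a 180 s
cutoff period (0.0056 Hz).  The spike detector is a documented substitute
(robust z of the global mean signal, threshold 3.5, configurable) for an
unpublished in-house algorithm.  Cue regressors default to 0.5 s boxcars.

## Scoring conventions

Signature scores are plain masked dot products; maps and signatures must
share grid and affine to $10^{-4}$ per element — there is no implicit
resampling, because resampling changes dot products.  An explicit
`regrid()` (nearest or trilinear) exists for deliberate use.  When masks
differ the intersection is used and the voxel count is attached to the
result.  For negative-weight subregions of a signature, a more positive
local pattern response means *deactivation*; the subregion's declared sign
travels with the value.  Whether a study's dot products used the signature
mask or a gray-matter intersection is generally unknowable from text;
intersection is this package's default.

## Exclusion rules

Trials are dropped when the intensity-rating reaction time is strictly
above 5.01 s or strictly below 0.02 s (boundary values retained; missing
treated as non-response).  Participants are then dropped when any
modality-by-condition cell retains trials at fewer than two of the three
stimulus levels.  The two published phrasings of the completeness rule
("complete sets ... for more than one stimulus level" vs "full data for at
least two stimulus levels") are reconciled as that post-condition.  Trial
exclusion precedes the participant rule, matching the printed order; both
filters are idempotent.

## Design decisions on open points

* Rank ties in the individual-difference analyses are averaged (no tie rule
  is stated anywhere).
* Missing participant-by-cell contrasts propagate as absent rows; nothing
  is imputed.
* Sex/age-style robustness covariates enter the fixed part only.
* The completeness rule is applied after trial exclusion.
* Satterthwaite steps and the information pseudo-inverse are as described
  above.
* `cohens_d()` is the descriptive across-participant mean/SD ratio and
  deliberately ignores the family structure.

## Known limitations

* The REML engine supports the two model shapes used here (factorial mains
  with optional interaction, plus fixed covariates) — it is not a general
  formula interface.
* The Bayes-factor sampler uses an independent-coordinate proposal; strong
  posterior correlation between `g` parameters would reduce its efficiency
  (the effective-sample-size guard would flag this).
* Heteroskedastic residual strata use a dense per-cluster path that is
  quadratic in cluster size; it is intended for small Welch-type problems.
* NIfTI support is deliberately minimal: uncompressed little-endian
  NIfTI-1, float32 output, sform affines only.

## What the tests establish

The test suite separates exact oracles (triple-loop dot products, balanced
one-way ANOVA estimators, Welch degrees of freedom, the JZS one-sample
quadrature), independent-implementation equivalence (lme4 on
single-zygosity data, used only in tests), and stochastic calibration (200
recovery replicates at a 100-family scale for bias and CI coverage of the
planted placebo effect; 1000 null replicates for the type-I error of the
Satterthwaite test; Bayes-factor sign calibration under planted effects and
nulls).  Simulation sizes in the suite are scaled-down versions of the
stated world chosen before the tests were first run; they are documented in
`tests/testthat/test-acceptance.R` and are not adjusted to outcomes.
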