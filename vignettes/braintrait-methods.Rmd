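---
title: "Methods: brain-trait association across regions, networks, and whole-brain patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-trait association across regions, networks, and whole-brain patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Task-fMRI studies of negative affectivity ask at which level of brain
organization a trait like neuroticism is represented: in the activity of
single theory-nominated regions (amygdala, anterior insula, dACC), in the
average activity of canonical resting-state networks, or in distributed
whole-brain activation patterns. Answering this fairly requires running a
battery of analyses of increasing flexibility under strict out-of-sample
discipline, because between-person effect sizes in this literature are small
(cross-validated correlations of .1-.3) while within-person state effects are
enormous (r near .9), and because a family of seemingly innocuous design
choices (task, baseline contrast, image scaling, outcome, algorithm) can
change the answer.

`braintrait` implements that battery end to end, together with a calibrated
synthetic-data generator so every stage can be exercised and tested without
access to any restricted cohort data.

# The generative model behind the synthetic cohorts

Each subject $i$ contributes trial maps for negative and neutral picture
trials on a 3-D voxel grid:

$$
X_{itv} = g^{(0)}_i
        + \mathbb{1}[\text{neg}]\,\big(g_i + h_{i,\mathrm{net}(v)}
        + \beta_T\, b_i\, w^{T}_v\big)
        + \beta_S\, a_{it}\, w^{S}_v + e_{itv},
$$

with

* $g^{(0)}_i \sim N(0, \sigma_{\mathrm{baseline}}^2)$ a per-person baseline
  offset shared by all trials. It cancels exactly in condition contrasts but
  survives implicit-baseline contrasts.
* $g_i \sim N(0, \sigma_{\mathrm{global}}^2)$ a per-person *reactivity*
  offset applied to negative trials: the "whole-brain bias". It survives the
  condition contrast, inflates between-network correlations, and is removed
  exactly by image-wise centering (a constant across voxels).
* $h_{i,k} \sim N(0, \sigma_{\mathrm{network}}^2)$ per-person per-network
  reactivity offsets. The ratio
  $\sigma_{\mathrm{global}}^2 / (\sigma_{\mathrm{global}}^2 + \sigma_{\mathrm{network}}^2)$
  sets the mean between-network correlation; the defaults (0.5, 0.35) put it
  near .67.
* $a_{it} = \mu_{c(t)} + s_i\,\mathbb{1}[\text{neg}] + v_{it}$ the latent
  state intensity ($\mu_{\text{neg}} = +1$, $\mu_{\text{neu}} = -1$,
  $v_{it} \sim N(0, \sigma_{\mathrm{state}}^2)$), which also drives the
  self-reported rating: $\mathrm{round}(\mathrm{clip}_{[1,5]}(3 + a_{it} +
  \varepsilon))$ with rating noise added *before* rounding. $s_i$ is the
  person's stable negative reactivity.
* $w^{S}$ the distributed, predominantly positive state pattern
  (region-smooth noise plus a positive shift, unit norm);
* $w^{T}$ the sparse trait pattern: per-region random signs, constant within
  region, restricted to the support networks (by default ~15% of voxels in
  the somatomotor network), mean-centered over its support so it is immune
  to global and network offsets, unit norm.
* $b_i$ the brain-coupled trait: the facet-specific (non-domain) part of
  vulnerability to stress.

Condition contrast maps are computed from the trial maps exactly as an
analysis would (mean negative minus mean neutral trials), so every signal and
offset propagates into them mechanically rather than by construction. A
second, signal-free "faces" task with the same offset structure is generated
at the contrast level.

## The trait hierarchy

Questionnaire scores are generated from one shared domain factor $d$ and six
facet-specific factors $u_j$: facet latents are
$\lambda d + \sqrt{1-\lambda^2}\, u_j$ with $\lambda = .65$; the domain score
reflects the shared factor $d$ itself (facet-specific variance enters only
the facet scores). Only the vulnerability-specific factor
$u_{\mathrm{vuln}}$ is coupled to the brain. This is why the domain-level
search must fail while the facet-level search succeeds: the domain score is
uncorrelated with the brain-coupled factor by construction, while the
vulnerability facet loads on it at
$\sqrt{1-\lambda^2}$. Convergent (negative affect), discriminant (positive
affect, extraversion), clinical (trait anxiety, depressive symptoms),
other-report, and task-rating outcomes are generated with fixed loadings on
$d$, $u_{\mathrm{vuln}}$, or nothing. All observed scores are attenuated to a
configurable reliability (default .8; observed = $\sqrt{\rho}\,\text{latent}
+ \sqrt{1-\rho}\,\text{noise}$), so halving reliability demonstrably lowers
every observable brain-trait correlation.

## Two routes from trait to brain

The vulnerability factor reaches the maps through two channels:

1. the localized contrast-level pattern $\beta_T b_i w^T$, and
2. a diffuse route: latent reactivity is correlated with the vulnerability
   factor ($\mathrm{cor}(s_i, b_i) = 0.3$ by default), so part of the trait
   signal rides on the distributed state pattern $w^S$.

The second channel mirrors the empirical observation that successful trait
patterns in this regime resemble domain-general responsiveness to stimulation
rather than an emotion-specific map. It also means that, by sampling
accident, *any* trait score that happens to correlate with reactivity in a
finite cohort acquires some decodability — a realistic nuisance that makes
outcome rankings noisy at small n, exactly as in real multiverse sweeps.
Setting `reactivity_trait_cor = 0` switches the channel off, which the test
suite uses when it needs strictly region-localized truth (e.g. for lesion
recovery).

## Calibration

The paper-scale summary statistics this regime reproduces (checked by the
test suite over seeds, not asserted from stored constants) are: mean
between-network correlations of condition contrasts in [.55, .80];
within-person decoding of trial ratings of at least .8 on average; training
cross-validated correlations for the vulnerability facet around .1-.2 and
hold-out correlations in [.1, .35]. The constants `beta_trait = 0.6`,
`beta_state = 3`, `sigma_noise = 1`, `sigma_state = 0.8`,
`sigma_reactivity = 0.5` were chosen once to land in this regime; trial-level
variance components are not reported in the literature this emulates, so
they are calibration choices, not estimates.

Trials follow a counterbalanced ABBA condition sequence so that any odd/even
trial split (the deterministic split-half scheme) contains both conditions.

# Preprocessing

* **Image-wise scaling** (`scale_images`): `center` subtracts each
  observation's mean across voxels (removing per-person constants exactly),
  `zscore` additionally divides by the row SD (sample, n-1 convention). A
  provenance record prevents double scaling and prevents applying a trained
  model to pre-scaled maps.
* **Voxel-wise standardization** (`standardize_voxels`): each voxel is
  z-scored on *training-sample* statistics; inside cross-validation the
  statistics are computed per training fold (inner folds use inner-training
  statistics only). Zero-variance voxels are set to 0 rather than dropped so
  voxel spaces stay aligned across pipeline stages.
* **Outlier exclusion** (`detect_outliers`): squared Mahalanobis distance on
  a low-dimensional feature set (the intended use is the seven network
  averages), chi-square p-values, Holm correction across observations.

# The model search

Nested cross-validation follows the 2x5x5 scheme: five inner folds select the
hyperparameter by the Pearson correlation of pooled inner out-of-fold
predictions (ties go to the simpler model — fewer components, smaller cost);
five outer folds produce held-out predictions; two repeats with fresh fold
assignments. Performance is always the correlation of pooled out-of-fold
predictions with the outcome, per repeat. Fold assignment is random under the
scheme's seed (not stratified). Folds with constant predictions score r = 0
with a warning rather than NA, so multiverse aggregation never propagates
missing values.

Algorithms: PLS (SIMPLS, implemented in the package so one decomposition
yields the whole component path — this is what makes permutation tests with
full re-tuning affordable), PCR (SVD path), linear-kernel SVR (e1071), and
PCA + random forest (components capped at the training-sample size and rank,
500 trees). Default grids: components {1, 2, 5, 10, 20} capped at half the
training n; SVR cost 10^-3..10^2 with epsilon fixed at 0.1 sd(y). These
grids are configuration, not estimates.

The permutation test re-runs the *entire* nested procedure per permuted
outcome; p = (1 + #{null >= observed}) / (1 + n_perm), one-tailed. The
hold-out sample is set aside once by quantile-bin stratification on the
outcome (sizes may differ by one or two from the nominal fraction due to
per-bin rounding), never touched during selection, and scored once with a
one-sided correlation test, a two-sided 95% Fisher-z interval, and a
one-sided stretched-beta Bayes factor.

## The correlation Bayes factor

`correlation_bf` integrates the exact reduced likelihood of an observed
correlation r given the population correlation rho,

$$
p(r \mid \rho) \propto (1-\rho^2)^{(n-1)/2} (1-\rho r)^{(3-2n)/2}
\; {}_2F_1\!\left(\tfrac12, \tfrac12; n-\tfrac12; \tfrac{1+\rho r}{2}\right),
$$

over a stretched-beta prior ((rho+1)/2 ~ Beta(1/kappa, 1/kappa)), truncated
to positive rho for one-sided tests, using adaptive quadrature (the Gauss
series for the hypergeometric term is evaluated in log space). The default
prior scale is kappa = 1/3, the conventional "medium" default of correlation
Bayes-factor software; kappa = 1 (uniform) is available. For the worked
example r = .19, n = 102 the medium prior gives 2.504; printed values of
2.53 in the literature correspond to the same prior evaluated at the
unrounded observed correlation (r of about .192). A "narrower" prior scale
reproducing a printed 3.09 is not numerically specified anywhere we could
verify, so no such default is shipped; the suite validates the integrator
against an independent quadrature, Monte-Carlo prior integration, and the
simulated sampling density of r instead.

# Interrogating a trained pattern

* **Virtual lesioning** removes all voxels of a region or network and, by
  default, *retrains* the final model on the reduced voxel space before
  re-evaluating on the hold-out sample (`retrain = FALSE` merely zeroes the
  removed weights; both are exposed because published lesion analyses rarely
  state which was done, and retraining is the stronger claim).
* **Weight thresholding** bootstrap-resamples the training sample, refits the
  linear model, and thresholds voxels by a two-sided percentile-bootstrap
  sign p-value (add-one smoothed) before removing connected components
  (6-connectivity) smaller than the cluster threshold. A normal reference on
  the bootstrap z = mean/SD was rejected: under null simulations its z values
  are overdispersed (SD about 1.14), which makes deep-tail p-values — the
  ones FDR uses — anticonservative. The percentile p's resolution is bounded
  by 2/(n_boot+1), so FDR thresholding with the default 500 resamples is
  conservative by construction.
* **Psychometrics**: split-half reliability rebuilds contrast maps from
  odd/even trial halves (deterministic; random halves behind a seed),
  correlates the two pattern expressions across subjects and applies the
  Spearman-Brown correction 2r/(1+r). Convergent/discriminant validity uses
  leave-one-out predictions of the target trait correlated with every listed
  trait. Within-person decoding trains on trial maps with folds split *by
  subject* — the only leakage-free reading when trials are nested in people —
  and reports the mean and SD of per-subject correlations between predicted
  and actual ratings. Centering makes the decoder invariant to per-subject
  constant offsets, which is precisely why state decoding survives the
  offsets that poison between-person prediction.

# The multiverse

Stage 1 crosses task (scenes/faces) x baseline (condition contrast /
implicit) x image scaling (none/center/zscore) with the neuroticism domain,
PLS, training sample: 12 models. Stage 2 multiplies in the seven neuroticism
scores and three linear algorithms: 252. Stage 3 expands to 14 affective
outcomes and seven algorithm-sample combinations (PLS/PCR/SVR on training and
full samples, PCA-forest on training only): 1,176 under the reference
configuration. The exact stage-3 crossing is explicit configuration — the
grid builder reports whatever its factor lists imply — because the reference
total constrains but does not uniquely determine it.

Every design point runs under the same cross-validation seed policy, so
identical points give identical rows and the sweep is order-invariant.
Failures are trapped per point. Meta-analysis is descriptive, since the ten
fold correlations of one model are dependent: a 1,000-tree bagged forest
(mtry = all factors) regresses fold correlations on design factors with
permutation importance expressed as the increase in out-of-bag RMSE, and a
crossed random-intercept model (REML, variances truncated at zero by the
fitter) attributes SDs to each factor and the residual. Aliased factors are
rejected with an error naming the pair. The hosted-app replacement is a
static export: tidy CSV plus a self-contained filterable HTML table.

# Problem sizes used by the test suite

The default generator configuration (200 subjects, 12x12x12 grid = 1,728
voxels, 40 regions, 15+15 trials) is the package's documented study
condition. Simulation suites that repeat the full staged pipeline across
many seeds use the reduced profile `reduced_sim_config()` (120 subjects,
8x8x8 grid, 24 regions), and type-I-error suites use small matrix problems
(n of 30-60, 15-20 features) with 99-permutation tests — sizes chosen so the
whole battery runs in minutes while leaving every statistical property
intact. The outcome-ranking check uses 300-subject cohorts because rankings
across seven outcomes at n = 120 are dominated by chance correlations with
reactivity (see "Two routes" above) — itself an instructive property of the
regime.

# Known limitations

* Generation starts at trial/contrast level: no hemodynamics, no GLM, no
  realignment or smoothing; masks and atlases are synthetic stand-ins with
  the interfaces (but not the anatomy) of published ones.
* Gaussian, spatially unstructured voxel noise (beyond region/network
  structure); real spatial autocorrelation is not emulated, so cluster-extent
  behavior on real data will differ.
* The trait hierarchy is a fixed two-level factor model with one
  brain-coupled facet; cross-loadings beyond those documented above are not
  modeled.
* Passing recovery tests shows the pipeline recovers the structure this
  generator plants at these sizes — not that any particular real dataset
  contains such structure.
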