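---
title: "Estimating wildlife abundance from automated drone detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wildlife abundance from automated drone detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavabund)
```

## The estimation problem

Thermal cameras on drones, paired with an automated detector, count warm
objects along flight lines. Relative to a human survey three error
processes matter:

* **imperfect detection** — some animals present are never flagged;
* **false detection** — warm objects that are not the target species are
  flagged as if they were;
* **duplicate detection** — overlap in the camera's field of view between
  adjacent flight lines records the same animal twice from different
  angles.

A raw detector count therefore mixes upward biases (false positives,
duplicates) with a downward one (missed animals), and neither classical
distance sampling nor standard N-mixture models address all three at once.
`uavabund` implements two routes and the machinery to compare them.

## Route 1: the modified Horvitz–Thompson estimator

For the $C$ objects the detector flags in one survey,
$$\hat N = \sum_{i=1}^{C} \frac{1 - \hat d_i - \hat f_i}{\hat p_i},$$
with $\hat p_i$ the probability an animal with object $i$'s covariates is
detected, $\hat f_i$ the probability object $i$ is false, and $\hat d_i$
the probability it is a duplicate. Each term is an inverse-probability
weight whose numerator discounts the chance the object should not be
counted at all.

One typographic note: a rendered form of this estimator can be read as
dividing only $\hat f_i$ by $\hat p_i$. We implement the subtractive
numerator $(1 - \hat d_i - \hat f_i)$ throughout, because the interval
logic of the estimator — the estimate must *increase* when detected
objects are unlikely to be false or duplicated, and *decrease* when those
probabilities are high — holds only for that form.

### The three Bernoulli models

All three probabilities come from logit-link Bernoulli regressions fitted
to ground-truthed data (`build_response()` derives each response):

| role      | rows used                                   | response = 1        | candidate covariates |
|-----------|---------------------------------------------|---------------------|----------------------|
| detection | verified detections and ground-truthed misses | detected            | temperature (°C), wind speed (km/h), distance to habitat edge (m) |
| false     | all detector output (misses excluded)        | false detection     | same three           |
| duplicate | verified animal detections only              | duplicate           | distance to nearest detection (m), time since previous detection (s) |

Warm weather and wind degrade thermal contrast and image stability, and
animals deep in the forest core (large habitat-edge distance) sit under
more canopy; all three are expected to suppress detection. False positives
concentrate near habitat edges; duplicates are close in space and time to
another detection.

`stepwise_select()` performs the selection: univariate GLMs are ranked with
the null model by p-value, residual-deviance reduction and AIC; covariates
with Wald $p < \alpha$ advance ($\alpha = 0.05$ by default — the
conventional threshold, exposed as an argument); all combinations of
advanced covariates are fitted; finally the penalized-spline additive
version of the best linear model (fitted with `mgcv`, GCV-chosen smoothing,
effective degrees of freedom counted toward AIC) is adopted only when it
improves AIC by **more than 2 points**. AIC is the operative selector; the
other two criteria are reported in the ranking table so disagreements are
visible rather than hidden. Ties break toward fewer parameters.

Two deliberate strictness choices: perfect separation is an **error**, not
a huge-coefficient fit, because downstream estimation divides by
$\hat p_i$; rank-deficient designs are likewise rejected.

### Intervals and clamping

`predict_with_ci()` forms $\hat\eta \pm z\,\mathrm{SE}(\hat\eta)$ on the
link scale ($z = 1.96$ for 95%) and maps through the inverse logit, so
limits are ordered and inside $[0,1]$ by construction. The upper limit of
$\hat N$ substitutes the *lower* limits of $p$, $f$ and $d$
simultaneously, and vice versa; because all objects move together the
interval is conservative relative to treating objects independently.

Numerical guards in `modified_ht_point()`: each numerator is floored at 0
(an object judged almost surely false *and* duplicate cannot subtract
animals) and $\hat p_i$ is floored at $10^{-3}$ so no single object
contributes more than a thousand animals. The count of clamped objects is
carried on every estimate so truncation is never silent. Response-scale
predictions that underflow to numerical zero are floored at $10^{-12}$
before estimation and then handled by the same clamp.

$\hat d_i$ is predicted for every detector-identified object, including
probable false positives, even though the duplicate model is trained only
on verified animals — this mirrors how the estimator must be applied to
raw detector output, where an object's true class is unknown.

## Route 2: the generalized N-mixture model

For transects $t = 1,\dots,T$ visited $v = 1,\dots,V$ times with counts
binned into distance classes $b$:

* $M_t \sim \mathrm{NegBin}(\lambda_t, \alpha)$ with
  $\log \lambda_t$ linear in transect-level land-cover percentages
  (variance $\lambda + \lambda^2/\alpha$; $\alpha$ estimated on the log
  scale; a Poisson variant is available);
* $N_{tv} \sim \mathrm{Binomial}(M_t, \phi_v)$ — the **availability**
  convention: $\phi_v$, on the logit scale of visit-level weather
  covariates, is the probability an animal present is available on that
  visit. (Visit-varying detection is an alternative reading of this layer;
  we implement availability.)
* an available animal at perpendicular distance $x$ (uniform on the strip
  $[0, W]$, $W = 75$ m) is detected with key-function probability $g(x)$:
  uniform ($g = 1$) or half-normal ($g(x) = e^{-x^2/2\sigma^2}$), giving
  multinomial cell probabilities $\pi_b = \int_b g / W$ via the Gaussian
  error function. Detection covariates enter on the half-normal scale as
  $\log\sigma_t = \log\sigma_0 + \beta^\top \mathrm{covs}_t$.

`nmixture_loglik()` marginalizes $M_t$ by truncated summation to $K$. The
inner sum over available animals has a closed form — thinning a binomial
into multinomial cells is again multinomial with cell probabilities
$\phi_v \pi_b$ and remainder $1 - \phi_v \sum_b \pi_b$ — which the test
suite verifies against exhaustive enumeration of both latent layers.
Everything is computed in log space with log-sum-exp.

Numerical choices: $K$ defaults to the largest per-visit transect total
plus 100 (doubling $K$ at the fitted parameters moves the log-likelihood
by less than $10^{-6}$ in the test suite, so the truncation is benign);
optimization is BFGS with relative tolerance $10^{-10}$ from documented
starting values (abundance intercept from mean per-transect maxima
corrected for availability and detection, availability at logit 0,
$\sigma$ at $W/2$, dispersion at $\log 2$, slopes at 0); standard errors
come from the inverse numerical Hessian, and a non-positive-definite
Hessian flags SEs unavailable rather than failing the fit. During model
ranking a non-converging candidate is excluded with a warning, not fatal.

`total_abundance()` reports $\sum_t \hat\lambda_t$ — *expected* latent
abundance. Empirical-Bayes posterior totals of the realized $M_t$ are a
reasonable alternative we deliberately do not compute; with few transects
the two can differ noticeably.

Under the uniform key with negative-binomial abundance, $\phi$ and
$\lambda$ are only weakly identified (a smaller population always
available looks like a larger one rarely available). `nmixture_spec()`
therefore accepts `fix_phi = 1` to pin availability when the design cannot
separate the layers.

### Goodness of fit

`freeman_tukey_gof()` uses the discrepancy
$T = \sum_{t,v,b} (\sqrt{y} - \sqrt{\hat y})^2$ with
$\hat y_{tvb} = \hat\lambda_t \hat\phi_v \hat\pi_{tb}$, robust for small
counts. Replicate datasets are simulated from the fitted model; by default
each replicate's statistic is evaluated at the generating estimates (the
*plug-in* mode), with `refit = TRUE` available to refit every replicate.
Plug-in is the default because refitting hundreds of replicates is costly
and, under the null, the plug-in reference distribution is exactly
exchangeable with the observed statistic — the calibration test in the
suite exploits precisely this. Refitting gives slightly wider reference
distributions (it absorbs estimation noise) and can be preferred for final
reporting.

## The synthetic-survey generator

`sim_config()` fixes the generating conditions; its defaults emulate a
small two-site campaign of the kind the estimators were designed for: 11
surveys across two sites (5 + 6, three-week spacing through one season),
~18 animals truly present per survey, detection driven by temperature
(−0.188 per °C) and habitat-edge distance (−0.0233 per m) with the
intercept set so the mean detection probability over the covariate ranges
is about 0.79, ~11 false positives per survey placed preferentially near
habitat edges (logit slope −0.0324 per m), and duplicates spawned from
detected animals with probability decaying in nearest-detection distance
(−0.0228 per m) and positions jittered by up to 30 m to mimic field-of-view
overlap. Together these rates yield on the order of 250 observation rows
over the seven training-date surveys, with roughly 14 unique detections, 4
misses, 6 duplicates and 11 false positives per survey. Covariate ranges
(temperature 5–25 °C, wind 0–20 km/h, habitat-edge distance 0–200 m) are
documented defaults chosen as plausible survey conditions, not quantities
estimated from data.

`dist_nearest` and detection times are recomputed *post hoc* over all
detected objects (true, false and duplicate) in a survey, exactly as they
would be derived from real detector output where classes are unknown.

The repeated-count generator draws from the N-mixture model itself (9
transects × 5 visits, $\lambda = 4$ per transect, $\phi = 0.7$,
half-normal $\sigma = 40$ m, $\alpha = 5$), so recovery and calibration
tests are exact-model checks.

What the generator does **not** emulate: animal movement between visits,
spatial clustering of animals, weather that trends over a season rather
than being drawn independently per survey, detector confidence scores, and
covariate measurement error. Passing tests therefore demonstrate that the
estimators are correct *under their own assumptions* and recover known
structure at the study's scale — not that those assumptions hold in any
particular field system. In particular the exact conditional-logistic
structure assumed by the false and duplicate models holds only
approximately under the mechanistic generator, so exact-recovery tests for
those two slopes run against direct Bernoulli draws, while the detection
model (whose miss/detect process *is* the fitted Bernoulli model) is
tested through the full generator.

## Evaluation conventions

Coverage is boundary-inclusive: truth equal to an interval limit counts as
covered. Comparison metrics are mean bias, RMSE and interval coverage —
chosen because the estimators' failure modes (raw-count inflation versus
correction noise) separate cleanly on them. Experiment seeds derive from
one master seed by counter, so every summary is bit-reproducible.

Problem sizes used by the test suite and acceptance script were chosen to
keep statistical checks sharp at desk scale: 50 simulated campaigns (200
test surveys) for interval coverage, 200 transects × 4 visits for
N-mixture parameter recovery, 100 calibration runs × 99 bootstrap
replicates for goodness-of-fit uniformity, and 500 plug-in replicates for
the reported bootstrap p-value.

## Other conventions and limitations

* Distance bins are half-open $[lo, hi)$ with the final bin closed at the
  strip half-width; a distance of exactly 15 m falls in the second bin.
* Dates are ISO-8601; a survey is identified as `site_date`. Hold-out
  splits are by survey date only, reflecting temporal autocorrelation in
  weather covariates.
* Observation-fate counts are reported by the validator
  (`klass_composition()`) but never forced to match any fixed totals.
* Linear fits serialize to a flat key-value text file (coefficients plus
  covariance, enough to predict with intervals); additive fits do not — a
  spline basis with penalties is not meaningfully round-trippable through
  that format, so the CLI serializes the best linear model when a GAM wins
  selection.
* Mixed-effects (random site) variants of the detection models and
  open-population or spatially explicit N-mixture variants are out of
  scope.
* The H-T interval propagates only parameter uncertainty in $p$, $f$ and
  $d$; it ignores binomial sampling noise in which animals happened to be
  detected. Its strong simultaneous substitution compensates in practice
  (the coverage experiment in the test suite measures exactly this), but
  it is not a variance-based interval and should not be read as one.
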