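# uavabund

Abundance estimation for wildlife detected **automatically in drone (RPAS)
thermal imagery**. Automated detectors bring error sources that classical
abundance models do not expect: besides ordinary imperfect detection, they
flag warm objects that are not the target species (*false detections*) and
record the same animal more than once where overlapping flight lines view it
from different angles (*duplicate detections*). `uavabund` implements and
compares two estimation routes for such data, aimed at quantitative
ecologists working with automated aerial counts of cryptic species (the
motivating case is koalas in eucalypt woodland).

## The two estimators

**Modified Horvitz–Thompson estimator.** For the C objects a detector
identifies in one survey,

    N̂ = Σ_{i=1}^{C} (1 − d̂ᵢ − f̂ᵢ) / p̂ᵢ

where p̂ᵢ is the fitted probability that an animal with object *i*'s
covariates is detected at all, f̂ᵢ the fitted probability that object *i* is
a false detection, and d̂ᵢ the probability it is a duplicate. The three
probabilities come from Bernoulli (logit-link) regressions fitted to
ground-truthed survey data — detection on ambient temperature, wind speed
and distance to habitat edge; false detection on the same candidates;
duplication on distance to the nearest other detection and time since the
previous detection — selected stepwise by AIC, with a penalized-spline
additive variant adopted only when it beats the linear model by more than 2
AIC points. 95% limits for N̂ substitute the per-object limits of p̂, f̂
and d̂ (lower limits of all three give the upper limit of N̂, and vice
versa).

**Generalized N-mixture model.** Repeated visits to strip transects give
counts binned by perpendicular distance (default 0–15–30–45–60–75 m).
Latent abundance per transect is negative-binomial with log-linear
land-cover covariates; availability per visit is binomial on the logit
scale of weather covariates; detection follows a uniform or half-normal
distance key function integrated over the bins. The latent abundance is
marginalized by truncated summation, candidate structures are ranked by
AIC, and fit is checked with a Freeman–Tukey parametric bootstrap.

A synthetic-survey generator (`sim_config()`, `simulate_observations()`,
`simulate_transect_counts()`) produces both data products with recorded
truth, so detection-model recovery, interval coverage and goodness-of-fit
calibration can be tested end to end without field data.

## Worked example

```r
library(uavabund)

cfg   <- sim_config()                       # two-site, 11-survey campaign
sim   <- simulate_observations(cfg, seed = 42)
split <- split_by_date(sim$table, tail(sort(unique(sim$table$date)), 4))

sel <- stepwise_select(split$train, "detection")
sel
#> Stepwise selection, role = detection (alpha = 0.05)
#>                       model type  n_par residual_deviance    p_value    aic selected
#> 1 GAM:dist_edge+temperature  GAM 3.7289            129.30 2.3476e-05 136.76    FALSE
#> 2     dist_edge+temperature  GLM 3.0000            131.88 7.3560e-06 137.88     TRUE
#> 3                 dist_edge  GLM 2.0000            139.87 9.0346e-06 143.87    FALSE
#> ...
```

The bivariate GLM is selected: the additive fit is better by only ~1.1 AIC,
short of the 2-point rule. Estimating the four held-out surveys and scoring
them against the generator's truth:

```r
fits <- list(p = sel$selected,
             f = stepwise_select(split$train, "false")$selected,
             d = stepwise_select(split$train, "duplicate")$selected)
est <- estimate_surveys(filter_detected(split$test), fits$p, fits$f, fits$d)
assess_coverage(est, data.frame(survey_id = sim$truth$per_survey$survey_id,
                                truth = sim$truth$per_survey$true_N))
#>          survey_id truth estimate lower upper covered
#> 1 north_2018-04-26    18       11     4    21    TRUE
#> 2 south_2018-04-12    18       13     6    23    TRUE
#> 3 south_2018-05-03    18       17     7    31    TRUE
#> 4 south_2018-05-24    18       15     7    26    TRUE
#> coverage: 4 / 4 surveys (100.0%)
```

Raw counts of 19–29 detected objects per survey shrink to estimates of
11–17 once false and duplicate detections are discounted, and every 95%
interval contains the true 18 animals. The N-mixture route on the
repeated-count design:

```r
simc <- simulate_transect_counts(cfg, seed = 42)
fit  <- fit_nmixture(simc$counts, nmixture_spec("halfnormal"))
fit
#> Generalized N-mixture fit: p[Half-normal] phi[1] lambda[1]
#>   logLik = -153.392, AIC = 314.78 (K = 106)
#>   ... total expected abundance = 31.5
freeman_tukey_gof(fit, n_sim = 500, seed = 1)
#> Freeman-Tukey parametric bootstrap: T = 71.004, p = 0.764 (500 sims, plug-in)
```

against a true latent total of 40 — adequate fit (p = .76) but a wide
margin on the total, reflecting how weakly availability and abundance are
separated by 9 transects.

A command-line wrapper (`inst/cli/uavabund.R`) exposes the same pipeline as
`simulate | fit-detection | estimate | nmix | evaluate | compare`
subcommands; see `Rscript inst/cli/uavabund.R --help` after installation.

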