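# thermhab

Thermal habitat models for demersal marine fish, built and stress-tested
against the *design* of the data that trains them.

## The problem

Species distribution models for fish like black sea bass are routinely
fitted as generalized additive models (GAMs) of presence–absence on
bottom temperature, then coupled to ocean model hindcasts to map
habitat. But different data sources — a shelf-wide spring/fall trawl
survey, a shallow inshore survey locked to two narrow temperature
windows, a year-round state survey, fishery-dependent observer records,
laboratory respirometry — sample very different slices of the thermal
environment, and the fitted curves inherit those gaps. `thermhab` is a
workflow for quantifying that sensitivity on synthetic data where the
true thermal response is known.

The core model is a penalized-spline binomial GAM,

    logit P(presence) = s(T),    s = thin plate spline, null space penalized

(`mgcv`, basis `"ts"`, REML), with a Poisson-family log-link analogue
for laboratory aerobic scope. Each fitted curve reports deviance
explained, the thermal optimum T_opt (argmax, defined only for curves
that steadily rise then fall), and the positive response range (where
fitted log-odds > 0, i.e. P > 0.5). Validation uses rank-based AUC under
100-iteration 75/25 Monte-Carlo CV and rolling 7-year block CV, a
cross-survey AUC matrix, and a decile habitat-quality-ranking scheme
that puts survey and laboratory models on a common 0–1 scale over
0–30 °C. Modelled temperatures are first bias-corrected against a
depth-resolved decadal-monthly climatology (decadal mean, bin-averaged
to the climatology grid, differenced, subtracted by decade and month).

The package covers the full chain: a seeded synthetic world
(temperature truth + biased "hindcast" + exact climatology + five
survey designs + lab experiment), the bias-correction and tow-matching
step, curve fitting and descriptors, the validation suite, and seasonal
habitat-quality projection. The staged workflow lives in `analysis/`
(`01_simulate_world.R` … `06_project.R`), each a thin driver over
package functions that prints what it found and writes tables under
`results/`.

## Worked example

Simulate a year-round survey of 5,000 tows over a 31-year world whose
true response is a dome peaking at 18 °C with limits 8.5/26.5 °C, apply
the bias correction, fit the curve, and cross-validate:

```r
library(thermhab)
world <- gen_temperature_world(grid_spec(c(38, 40), c(-75, -73),
                                         res_model = 0.1, res_clim = 0.2),
                               years = 1985:2015, seed = 7)
params <- true_response_params("dome", t_opt = 18, t_low = 8.5,
                               t_high = 26.5, p_max = 0.8)
cfg <- survey_config("DEMO", 1985:2015, 1:12, c(38, 40), c(5, 150), 5000)
tows <- gen_survey_dataset(cfg, world, params, seed = 1)

biases <- setNames(lapply(names(world$clim), function(d)
  compute_bias_field(
    decadal_monthly_mean_regrid(world$model, d, world$clim[[d]]),
    climatology_bottom(world$clim[[d]]))), names(world$clim))
corrected <- apply_bias(world$model, biases)
tows$temp_model_c <- match_trawls(tows, corrected)

curve <- fit_presence_curve(tows$temp_model_c, tows$presence)
curve
curve_descriptors(curve)
cv <- monte_carlo_cv(tows$temp_model_c, tows$presence, n_iter = 100, seed = 1)
cv
all(cv$auc >= 0.6)
```

which prints

```
thermal_curve (binomial_logit): deviance explained 4.8%, data range 1.3-24.8 C
$t_opt          18.7
$positive_range 8.02 28.19     (upper end beyond the sampled range -> warning)
$unimodal       TRUE
cv_result (random_mc): 100 iteration(s), AUC mean 0.639, range 0.607-0.671
[1] TRUE
```

The fitted optimum lands within a degree of the generating 18 °C, the
positive range brackets the true 8.5–26.5 °C (its upper end is an
extrapolation past the warmest sampled water, and is flagged as such),
and every CV iteration clears the AUC 0.6 predictive-value rule.

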