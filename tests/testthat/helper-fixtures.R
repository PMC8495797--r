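# Shared fixtures, built once per test run. Small domain, full 31-year
# record so decade and block logic is exercised end to end.

tiny_grid <- function() {
  grid_spec(lat_range = c(38, 40), lon_range = c(-75, -73),
            res_model = 0.1, res_clim = 0.2, max_depth = 400)
}

# one shared world for read-only tests (never mutated)
shared_world <- gen_temperature_world(tiny_grid(), years = 1985:2015, seed = 42)

dome_params <- function(p_max = 0.8)
  true_response_params("dome", t_opt = 18, t_low = 8.5, t_high = 26.5,
                       p_max = p_max)

# all decadal bias fields of a world
world_biases <- function(world) {
  out <- lapply(names(world$clim), function(d)
    compute_bias_field(
      decadal_monthly_mean_regrid(world$model, d, world$clim[[d]]),
      climatology_bottom(world$clim[[d]])))
  stats::setNames(out, names(world$clim))
}

# analytic curve helper: build a thermal_curve from a link-scale function
analytic_curve <- function(f, family = "binomial_logit",
                           data_range = c(0, 30)) {
  tg <- seq(0, 30, by = 0.1)
  thermal_curve(tg, f(tg), family = family, data_range = data_range)
}

# brute-force pairwise AUC oracle (ties count one half)
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
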