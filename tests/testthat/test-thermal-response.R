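test_that("temperature-independent presence yields a flat, uninformative curve", {
  d <- sim_presence_tows(5000, params = NULL, prevalence = 0.3, seed = 1)
  curve <- fit_presence_curve(d$temp, d$presence)
  expect_lt(curve$deviance_explained, 0.01)
  expect_gte(curve$deviance_explained, 0)
  # within +-2 SE of the flat logit(prevalence) line over the sampled range
  keep <- curve$t_grid >= 2 & curve$t_grid <= 27
  flat <- qlogis(mean(d$presence))
  expect_true(all(abs(curve$lp[keep] - flat) <= 2 * pmax(curve$se[keep], 1e-6)))
})

test_that("the fitted peak recovers the analytic optimum of a quadratic logit", {
  # generating model: logit P = b0 + b1 t + b2 t^2, argmax = -b1 / (2 b2)
  b0 <- -6.4; b1 <- 0.72; b2 <- -0.02   # analytic argmax 18
  argmax <- -b1 / (2 * b2)
  set.seed(99)
  temp <- runif(20000, 2, 27)
  p <- plogis(b0 + b1 * temp + b2 * temp^2)
  presence <- runif(20000) < p
  curve <- fit_presence_curve(temp, presence)
  fitted_argmax <- curve$t_grid[which.max(curve$lp)]
  expect_lt(abs(fitted_argmax - argmax), 0.5)
})

test_that("penalization keeps perfectly separated fits finite", {
  temp <- c(seq(5, 14.5, length.out = 20), seq(15.5, 25, length.out = 20))
  presence <- temp > 15
  curve <- suppressWarnings(fit_presence_curve(temp, presence))
  expect_true(all(is.finite(curve$lp)))
  expect_equal(compute_auc(curve_response(curve, temp), presence), 1.0)
})

test_that("degenerate or malformed presence data are rejected", {
  expect_error(fit_presence_curve(1:60, rep(TRUE, 60)), "degenerate")
  expect_error(fit_presence_curve(c(1, NA, 3), c(TRUE, FALSE, TRUE)),
               "non-finite")
})

test_that("lab scope curve peaks near the generating optimum", {
  lab <- gen_lab_scope(t_opt_lab = 24.8, n_per_temp = 12, noise_cv = 0, seed = 2)
  curve <- fit_scope_curve(lab)
  expect_identical(curve$family, "poisson_log")
  peak <- curve$t_grid[which.max(curve$lp)]
  expect_lt(abs(peak - 24.8), 1)
})

test_that("constant scope gives a flat curve and bad inputs error", {
  lab <- data.frame(temp_c = rep(c(12, 16, 20, 24, 28), each = 5), scope = 3)
  curve <- fit_scope_curve(lab)
  expect_lt(max(curve$lp) - min(curve$lp), 1e-6)
  expect_error(fit_scope_curve(data.frame(temp_c = c(12, 12, 20), scope = 1:3)),
               "distinct")
  expect_error(fit_scope_curve(data.frame(temp_c = c(12, 20, 28),
                                          scope = c(1, -1, 2))), "negative")
})

test_that("descriptors recover closed-form roots of an analytic curve", {
  # logit P = -(t - 18)^2 / 10 + 2: roots at 18 +- sqrt(20)
  curve <- analytic_curve(function(t) -(t - 18)^2 / 10 + 2)
  d <- curve_descriptors(curve)
  expect_true(d$unimodal)
  expect_equal(d$t_opt, 18)
  expect_equal(d$positive_range, 18 + c(-1, 1) * sqrt(20), tolerance = 1e-3)
  expect_false(d$open_low || d$open_high)
})

test_that("descriptors handle negative, plateau and noisy-peak curves", {
  neg <- analytic_curve(function(t) -1 - 0.01 * t)
  dn <- curve_descriptors(neg)
  expect_true(is.na(dn$t_opt))
  expect_null(dn$positive_range)

  # monotone rise crossing zero at 8.7, then flat: no optimum, open-ended
  # positive range above the single crossing
  plat <- analytic_curve(function(t) pmin((t - 8.7) * 0.8, 3))
  dp <- curve_descriptors(plat)
  expect_true(is.na(dp$t_opt))
  expect_false(dp$unimodal)
  expect_equal(dp$positive_range[1], 8.7, tolerance = 1e-6)
  expect_true(dp$open_high)

  # small wiggles (<5% of total variation) do not void the optimum
  wiggly <- analytic_curve(function(t) -(t - 18)^2 / 10 + 2 +
                             0.02 * sin(3 * t))
  expect_true(curve_descriptors(wiggly)$unimodal)
  # gross bimodality does void it
  bimodal <- analytic_curve(function(t) sin(t / 2.2))
  expect_false(curve_descriptors(bimodal)$unimodal)
})

test_that("descriptors warn when they extend beyond the sampled range", {
  curve <- analytic_curve(function(t) -(t - 18)^2 / 10 + 2,
                          data_range = c(15, 21))
  expect_warning(curve_descriptors(curve), "caution")
})

test_that("response scaling maps the grid extremes to 0 and 1", {
  curve <- analytic_curve(function(t) -(t - 18)^2 / 10 + 2)
  sf <- scale_response(curve)
  expect_equal(sf(18), 1.0, tolerance = 1e-9)
  tmin <- curve$t_grid[which.min(curve$lp)]
  expect_equal(sf(tmin), 0.0)
  expect_true(all(sf(seq(0, 30, 0.5)) >= 0 & sf(seq(0, 30, 0.5)) <= 1))

  # dome asymptotic to zero: min-max scaling ~ divide-by-max
  dome <- analytic_curve(function(t) -(t - 15)^2 / 4)
  sfd <- scale_response(dome)
  r <- plogis(dome$lp); tt <- dome$t_grid
  expect_lt(max(abs(sfd(tt) - r / max(r))), 0.01)

  flat <- analytic_curve(function(t) rep(0.3, length(t)))
  expect_error(scale_response(flat), "flat")
})

test_that("deviance explained lies in [0,1] for informative fits", {
  d <- sim_presence_tows(4000, dome_params(0.5), seed = 12)
  curve <- fit_presence_curve(d$temp, d$presence)
  expect_gt(curve$deviance_explained, 0.05)
  expect_lt(curve$deviance_explained, 1)
})

test_that("in situ and corrected-model fits give near-identical descriptors", {
  w <- shared_world
  params <- dome_params(p_max = 0.8)
  cfg <- survey_config("WIDE", 1985:2015, 1:12, c(38, 40), c(5, 150), 6000)
  tows <- gen_survey_dataset(cfg, w, params, seed = 31)
  corrected <- apply_bias(w$model, world_biases(w))
  tows$temp_model_c <- match_trawls(tows, corrected)
  c_insitu <- fit_presence_curve(tows$temp_insitu_c, tows$presence)
  c_model <- fit_presence_curve(tows$temp_model_c, tows$presence)
  d1 <- suppressWarnings(curve_descriptors(c_insitu))
  d2 <- suppressWarnings(curve_descriptors(c_model))
  expect_lt(abs(d1$t_opt - d2$t_opt), 1)
  expect_lt(max(abs(d1$positive_range - d2$positive_range)), 1)
})

test_that("narrow-window sampling loses the thermal optimum that wide sampling finds", {
  # the inshore-style design confined to two temperature windows cannot
  # see the decline past the optimum, so its curve reports no Topt, while
  # the wide year-round design recovers one near the generating value
  w <- shared_world
  params <- dome_params(p_max = 0.8)
  wide_cfg <- survey_config("WIDE", 1985:2015, 1:12, c(38, 40), c(5, 150), 4000)
  narrow_cfg <- survey_config("NARROW", 1985:2015, c(4:6, 9:11), c(38, 40),
                              c(5, 60), 2570,
                              temp_windows = list(c(5, 10), c(15, 20)))
  wide <- gen_survey_dataset(wide_cfg, w, params, seed = 8)
  narrow <- gen_survey_dataset(narrow_cfg, w, params, seed = 8)
  cw <- fit_presence_curve(wide$temp_truth_c, wide$presence)
  cn <- fit_presence_curve(narrow$temp_truth_c, narrow$presence)
  dw <- suppressWarnings(curve_descriptors(cw))
  dn <- suppressWarnings(curve_descriptors(cn))
  expect_true(dw$unimodal)
  expect_lt(abs(dw$t_opt - 18), 1.5)
  expect_false(dn$unimodal)
  expect_true(is.na(dn$t_opt))
  # and its sampled range is a strict subset of the wide design's
  expect_gt(diff(cw$data_range), diff(cn$data_range))
})
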