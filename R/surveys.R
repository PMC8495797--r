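#' Survey sampling configuration
#'
#' Describes one trawl survey's sampling design: years and months of
#' operation, latitudinal and depth coverage, tow count, and (optionally)
#' the bottom-temperature windows the design effectively samples, used to
#' emulate inshore surveys whose fixed seasonal timing confines tows to a
#' narrow slice of the annual temperature range.
#'
#' @param name survey label.
#' @param years integer years of operation.
#' @param months calendar months sampled (non-empty subset of 1-12).
#' @param lat_range latitudinal coverage, degrees N, ordered pair.
#' @param depth_range tow depth coverage, m, ordered pair.
#' @param n_tows number of tows to generate (> 0, or 0 for an empty set).
#' @param temp_windows optional list of `c(low, high)` degrees-C windows;
#'   tows are rejection-sampled until the true bottom temperature at the
#'   tow falls inside one of them.
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(name, years, months, lat_range, depth_range,
                          n_tows, temp_windows = NULL) {
  months <- sort(unique(as.integer(months)))
  if (!length(months) || any(months < 1 | months > 12))
    stop("months must be a non-empty subset of 1-12")
  if (n_tows < 0) stop("n_tows must be >= 0")
  if (lat_range[1] > lat_range[2] || depth_range[1] > depth_range[2])
    stop("ranges must be ordered")
  if (!is.null(temp_windows)) {
    stopifnot(is.list(temp_windows),
              all(vapply(temp_windows, function(w) length(w) == 2 && w[1] < w[2],
                         logical(1))))
  }
  structure(list(name = name, years = sort(as.integer(years)), months = months,
                 lat_range = lat_range, depth_range = depth_range,
                 n_tows = as.integer(n_tows), temp_windows = temp_windows),
            class = "survey_config")
}

#' Preset survey configurations for the Mid-Atlantic Bight designs
#'
#' Five designs spanning the contrasts that matter for thermal habitat
#' modelling: a shelf-wide spring/fall federal survey; a shallow inshore
#' spring/fall survey whose timing confines it to narrow temperature
#' windows (about 5-10 C in spring and 15-20 C in fall); a year-round
#' inshore state survey with wide temperature exposure; a geographically
#' confined sound survey; and a year-round fishery-dependent observer
#' set. Tow counts follow the historical sample sizes except the observer
#' set, which is scaled to 20,000 tows (the historical set is an order of
#' magnitude larger than any survey; the scaled set preserves that it is
#' the largest source while keeping simulation practical).
#'
#' @return Named list of [survey_config()] objects.
#' @export
survey_configs <- function() {
  list(
    NEFSC = survey_config("NEFSC", 1985:2015, c(2:6, 9:12),
                          c(33.5, 44.75), c(10, 350), 20690),
    NEAMAP = survey_config("NEAMAP", 2007:2015, c(4:6, 9:11),
                           c(35.1, 41.5), c(5, 60), 2570,
                           temp_windows = list(c(5, 10), c(15, 20))),
    NJDEP = survey_config("NJDEP", 1988:2015, c(1, 4, 6, 8, 10),
                          c(38.5, 40.5), c(5, 40), 5105),
    CTDEEP = survey_config("CTDEEP", 1985:2015, c(5:7, 9:11),
                           c(40.8, 41.4), c(5, 60), 5850),
    Observer = survey_config("Observer", 1989:2015, 1:12,
                             c(35, 44.5), c(10, 250), 20000)
  )
}

#' Generate one survey's tow records from a temperature world
#'
#' Tows are placed uniformly over the wet model cells whose centre
#' latitude and seafloor depth fall within the survey's coverage,
#' stratified uniformly over the survey's months and years. Each tow's
#' true bottom temperature is the world truth at its cell and month; the
#' recorded in situ temperature adds measurement noise, and presence is a
#' Bernoulli draw from the true response curve evaluated at the true
#' temperature. Surveys with `temp_windows` rejection-sample tow
#' (year, month, cell) triples until the true temperature falls in a
#' window (up to `max_tries` rounds, then remaining tows are kept as-is).
#'
#' @param cfg a [survey_config()].
#' @param world a [gen_temperature_world()] result.
#' @param params a [true_response_params()] generating curve.
#' @param seed integer seed; records are reproducible from it.
#' @param sigma_meas sd of in situ temperature measurement noise, degrees
#'   C (default 0.3).
#' @param max_tries rejection-sampling rounds for temperature windows.
#' @return data.frame with columns `survey, year, month, day, lat, lon,
#'   depth_m, temp_insitu_c, presence` plus the latent `temp_truth_c`
#'   (kept for simulation diagnostics; not part of the on-disk schema).
#' @export
gen_survey_dataset <- function(cfg, world, params, seed,
                               sigma_meas = 0.3, max_tries = 200) {
  stopifnot(inherits(cfg, "survey_config"),
            inherits(world, "temperature_world"),
            inherits(params, "true_response"))
  years <- intersect(cfg$years, world$years)
  if (!length(years))
    stop(sprintf("survey %s years have no overlap with world coverage", cfg$name))
  grid <- world$grid
  latm <- matrix(grid$lat_model, length(grid$lat_model), length(grid$lon_model))
  eligible <- which(grid$mask &
                      latm >= cfg$lat_range[1] & latm <= cfg$lat_range[2] &
                      grid$depth >= cfg$depth_range[1] &
                      grid$depth <= cfg$depth_range[2])
  if (cfg$n_tows == 0) {
    return(data.frame(survey = character(), year = integer(), month = integer(),
                      day = integer(), lat = numeric(), lon = numeric(),
                      depth_m = numeric(), temp_insitu_c = numeric(),
                      presence = logical(), temp_truth_c = numeric()))
  }
  if (!length(eligible))
    stop(sprintf("survey %s: no eligible wet cells in lat/depth coverage", cfg$name))

  nlat <- length(grid$lat_model)
  with_seed(seed, {
    n <- cfg$n_tows
    draw <- function(m) {
      cell <- sample(eligible, m, replace = TRUE)
      data.frame(year = sample(years, m, replace = TRUE),
                 month = sample(cfg$months, m, replace = TRUE),
                 cell = cell)
    }
    tows <- draw(n)
    truth_at <- function(d) {
      ti <- time_index(world$truth, d$year, d$month)
      world$truth$temp[cbind(ti, (d$cell - 1L) %% nlat + 1L,
                             (d$cell - 1L) %/% nlat + 1L)]
    }
    tows$temp_truth_c <- truth_at(tows)
    if (!is.null(cfg$temp_windows)) {
      in_window <- function(t) {
        ok <- rep(FALSE, length(t))
        for (w in cfg$temp_windows) ok <- ok | (t >= w[1] & t <= w[2])
        ok
      }
      tries <- 0L
      repeat {
        bad <- which(!in_window(tows$temp_truth_c))
        if (!length(bad) || tries >= max_tries) break
        repl <- draw(length(bad))
        repl$temp_truth_c <- truth_at(repl)
        tows[bad, c("year", "month", "cell", "temp_truth_c")] <-
          repl[, c("year", "month", "cell", "temp_truth_c")]
        tries <- tries + 1L
      }
    }
    ilat <- (tows$cell - 1L) %% nlat + 1L
    ilon <- (tows$cell - 1L) %/% nlat + 1L
    half <- grid$res_model / 2
    lat <- grid$lat_model[ilat] + stats::runif(n, -half, half)
    lon <- grid$lon_model[ilon] + stats::runif(n, -half, half)
    p <- eval_true_response(params, tows$temp_truth_c)
    data.frame(
      survey = cfg$name,
      year = tows$year, month = tows$month,
      day = sample(1:28, n, replace = TRUE),
      lat = lat, lon = lon,
      depth_m = grid$depth[cbind(ilat, ilon)],
      temp_insitu_c = tows$temp_truth_c + stats::rnorm(n, 0, sigma_meas),
      presence = stats::runif(n) < p,
      temp_truth_c = tows$temp_truth_c)
  })
}

#' Simulate presence-absence tows directly from a response curve
#'
#' Convenience generator for method studies that do not need the full
#' gridded world: temperatures are drawn uniformly over `temp_range`
#' (the shelf-wide 2-27 C sampled range by default), presence either from
#' a generating curve or, when `params` is `NULL`, independently of
#' temperature at a constant `prevalence` (the no-signal null case).
#'
#' @param n number of tows.
#' @param params a [true_response_params()] or `NULL` for the null case.
#' @param temp_range sampled temperature range, degrees C.
#' @param prevalence constant presence probability for the null case.
#' @param years calendar years to attribute tows to (uniform).
#' @param seed integer seed.
#' @return data.frame with columns `temp`, `presence`, `year`.
#' @export
sim_presence_tows <- function(n, params = NULL, temp_range = c(2, 27),
                              prevalence = 0.3, years = 1985:2015, seed = 1) {
  with_seed(seed, {
    temp <- stats::runif(n, temp_range[1], temp_range[2])
    p <- if (is.null(params)) rep(prevalence, n) else eval_true_response(params, temp)
    data.frame(temp = temp,
               presence = stats::runif(n) < p,
               year = sample(years, n, replace = TRUE))
  })
}
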