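#' Gridded monthly bottom-temperature field
#'
#' Container for a stack of monthly bottom-temperature grids on a regular
#' lat/lon grid with a wet/dry mask, the shape delivered by a regional
#' ocean hindcast after bottom extraction and monthly averaging.
#'
#' @param lat,lon regular grid centre coordinates, strictly increasing;
#'   latitude in degrees north, longitude in degrees east (negative west).
#' @param time data.frame with integer columns `year`, `month`, strictly
#'   increasing in calendar order.
#' @param temp numeric array of dim `(nrow(time), length(lat), length(lon))`.
#' @param mask logical matrix `(length(lat), length(lon))`, `TRUE` = wet.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(lat, lon, time, temp, mask) {
  stopifnot(is.numeric(lat), is.numeric(lon),
            all(diff(lat) > 0), all(diff(lon) > 0),
            is.data.frame(time), all(c("year", "month") %in% names(time)))
  key <- time$year * 12 + time$month
  if (any(diff(key) <= 0)) stop("time must be strictly increasing")
  if (any(time$month < 1 | time$month > 12)) stop("month must be in 1-12")
  if (!all(dim(temp) == c(nrow(time), length(lat), length(lon))))
    stop("temp dimensions do not match (time, lat, lon)")
  if (!all(dim(mask) == c(length(lat), length(lon))))
    stop("mask dimensions do not match (lat, lon)")
  structure(list(lat = lat, lon = lon,
                 time = data.frame(year = as.integer(time$year),
                                   month = as.integer(time$month)),
                 temp = temp, mask = mask),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field: %d time slices (%d-%02d to %d-%02d), %d x %d grid, %d wet cells\n",
              nrow(x$time), x$time$year[1], x$time$month[1],
              x$time$year[nrow(x$time)], x$time$month[nrow(x$time)],
              length(x$lat), length(x$lon), sum(x$mask)))
  invisible(x)
}

# Index of a (year, month) pair in a grid_field's time axis, or NA.
time_index <- function(field, year, month) {
  match(year * 12 + month, field$time$year * 12 + field$time$month)
}

#' Depth-resolved decadal-monthly climatology field
#'
#' Long-term decadal mean temperature at standard depth levels on a
#' regular lat/lon grid, one layer stack per calendar month. Levels
#' follow the standard scheme of 5 m spacing down to 100 m, 25 m to
#' 500 m and 50 m below that; levels below the seafloor are missing.
#'
#' @param decade decade label, e.g. `"1985-1994"`.
#' @param lat,lon regular grid centres, strictly increasing.
#' @param levels standard depths (m), strictly increasing.
#' @param temp numeric array `(12, length(levels), length(lat), length(lon))`,
#'   `NA` below the seafloor and on dry cells.
#' @param mask logical wet/dry matrix `(length(lat), length(lon))`.
#' @return An object of class `climatology_field`.
#' @export
climatology_field <- function(decade, lat, lon, levels, temp, mask) {
  stopifnot(all(diff(lat) > 0), all(diff(lon) > 0), all(diff(levels) > 0))
  if (!all(dim(temp) == c(12L, length(levels), length(lat), length(lon))))
    stop("temp dimensions do not match (month, level, lat, lon)")
  validate_level_scheme(levels)
  wet_idx <- which(mask)
  if (length(wet_idx)) {
    # every wet cell must carry at least one valid level in every month
    any_valid <- apply(!is.na(temp), c(1, 3, 4), any)
    for (m in 1:12) {
      bad <- mask & !any_valid[m, , ]
      if (any(bad)) stop("wet cell with no valid climatology level")
    }
  }
  structure(list(decade = decade, lat = lat, lon = lon, levels = levels,
                 temp = temp, mask = mask),
            class = "climatology_field")
}

# Standard level scheme: 5 m (0-100 m), 25 m (100-500 m), 50 m (> 500 m).
standard_levels <- function(max_depth) {
  lev <- c(seq(0, 100, by = 5), seq(125, 500, by = 25), seq(550, 2000, by = 50))
  lev[lev <= max(max_depth, 5)]
}

validate_level_scheme <- function(levels) {
  d <- diff(levels)
  ok <- (levels[-length(levels)] < 100 & d == 5) |
    (levels[-length(levels)] >= 100 & levels[-length(levels)] < 500 & d == 25) |
    (levels[-length(levels)] >= 500 & d == 50)
  if (!all(ok)) stop("levels do not follow the 5/25/50 m spacing scheme")
  invisible(levels)
}

#' Grid specification for the synthetic world
#'
#' Defines the spatial domain, the fine model grid resolution and the
#' coarser climatology grid resolution. The model grid is nested inside
#' the climatology grid (an integer refinement with offset centres) so
#' every model cell centre falls strictly inside one climatology cell.
#' Seafloor depth increases offshore (eastward) from a shallow coastal
#' band, with a strip of land along the western edge.
#'
#' @param lat_range,lon_range domain bounds, degrees.
#' @param res_model model grid resolution, degrees (default 0.05, about
#'   the 5-7 km of a regional hindcast).
#' @param res_clim climatology grid resolution, degrees (default 0.1).
#' @param max_depth deepest seafloor in the domain, m.
#' @return A list with model/climatology grid axes, the per-cell depth
#'   matrix and the wet/dry mask, of class `grid_spec`.
#' @export
grid_spec <- function(lat_range = c(37, 41.5), lon_range = c(-75.5, -71.5),
                      res_model = 0.05, res_clim = 0.1, max_depth = 400) {
  stopifnot(lat_range[1] < lat_range[2], lon_range[1] < lon_range[2])
  if (abs(res_clim / res_model - round(res_clim / res_model)) > 1e-9)
    stop("res_clim must be an integer multiple of res_model")
  lat_c <- seq(lat_range[1] + res_clim / 2, lat_range[2] - res_clim / 2, by = res_clim)
  lon_c <- seq(lon_range[1] + res_clim / 2, lon_range[2] - res_clim / 2, by = res_clim)
  lat_m <- seq(lat_range[1] + res_model / 2, lat_range[2] - res_model / 2, by = res_model)
  lon_m <- seq(lon_range[1] + res_model / 2, lon_range[2] - res_model / 2, by = res_model)
  frac <- (matrix(lon_m, length(lat_m), length(lon_m), byrow = TRUE) - lon_range[1]) /
    diff(lon_range)
  latm <- matrix(lat_m, length(lat_m), length(lon_m))
  depth <- max_depth * frac^2 * (1 + 0.05 * (39 - latm))
  mask <- depth >= 5
  structure(list(lat_range = lat_range, lon_range = lon_range,
                 res_model = res_model, res_clim = res_clim,
                 lat_model = lat_m, lon_model = lon_m,
                 lat_clim = lat_c, lon_clim = lon_c,
                 depth = depth, mask = mask),
            class = "grid_spec")
}

#' Generate a synthetic temperature world
#'
#' Builds a self-consistent trio of gridded products: (a) the true
#' monthly bottom temperature on the model grid, from a smooth seasonal
#' cycle damped with depth, a latitudinal gradient, offshore deep-water
#' stability and a shared AR(1) interannual anomaly; (b) a depth-resolved
#' decadal-monthly climatology on the coarser grid, computed as the exact
#' decadal monthly bin-average of the truth (no estimation error); and
#' (c) a "model" field equal to truth plus a known spatially varying bias
#' and optional noise, emulating a hindcast with a warm shelf bias.
#'
#' @param grid a [grid_spec()].
#' @param years integer years covered, within 1985-2015.
#' @param bias_fn function `(lat, lon, month) -> bias` in degrees C added
#'   to the truth to form the model field. Default: about +2 C with a
#'   gentle latitudinal modulation.
#' @param seed integer seed; the world is reproducible from it.
#' @param sigma_interannual sd (degrees C) of the AR(1) yearly anomaly.
#' @param rho_interannual AR(1) coefficient of the yearly anomaly.
#' @param model_noise_sd sd of independent cell-level noise added to the
#'   model field on top of the bias (0 = none).
#' @return A list of class `temperature_world` with elements `truth` and
#'   `model` ([grid_field()]s), `clim` (named list of
#'   [climatology_field()]s by decade), `grid`, `bias_fn`.
#' @export
gen_temperature_world <- function(grid = grid_spec(), years = 1985:2015,
                                  bias_fn = default_bias_fn,
                                  seed = 1,
                                  sigma_interannual = 0.4,
                                  rho_interannual = 0.6,
                                  model_noise_sd = 0) {
  if (length(years) == 0) stop("empty year range")
  years <- sort(as.integer(years))
  if (min(years) < 1985 || max(years) > 2015)
    stop("world years must lie within 1985-2015")
  nlat <- length(grid$lat_model); nlon <- length(grid$lon_model)
  time <- data.frame(year = rep(years, each = 12L),
                     month = rep(1:12, times = length(years)))
  nt <- nrow(time)

  D <- grid$depth
  latm <- matrix(grid$lat_model, nlat, nlon)
  t_deep <- 8
  t_surf <- 13 - 1.1 * (latm - 39)
  static <- t_deep + (t_surf - t_deep) * exp(-D / 150)
  amp <- 12 * exp(-D / 40)
  seas <- cos(2 * pi * (1:12 - 9) / 12)

  anom <- with_seed(seed, {
    a <- numeric(length(years))
    a[1] <- stats::rnorm(1, 0, sigma_interannual / sqrt(1 - rho_interannual^2))
    if (length(years) > 1)
      for (i in 2:length(years))
        a[i] <- rho_interannual * a[i - 1] + stats::rnorm(1, 0, sigma_interannual)
    a
  })

  truth <- array(NA_real_, c(nt, nlat, nlon))
  for (i in seq_len(nt)) {
    yi <- match(time$year[i], years)
    sl <- static + amp * seas[time$month[i]] + anom[yi]
    sl[!grid$mask] <- NA_real_
    truth[i, , ] <- sl
  }

  bias <- array(0, c(12L, nlat, nlon))
  lonm <- matrix(grid$lon_model, nlat, nlon, byrow = TRUE)
  for (m in 1:12) bias[m, , ] <- bias_fn(latm, lonm, m)

  model <- truth
  for (i in seq_len(nt)) model[i, , ] <- truth[i, , ] + bias[time$month[i], , ]
  if (model_noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, 7L),
                       array(stats::rnorm(length(model), 0, model_noise_sd), dim(model)))
    model <- model + noise
  }
  for (i in seq_len(nt)) {
    sl <- model[i, , ]; sl[!grid$mask] <- NA_real_; model[i, , ] <- sl
  }

  truth_f <- grid_field(grid$lat_model, grid$lon_model, time, truth, grid$mask)
  model_f <- grid_field(grid$lat_model, grid$lon_model, time, model, grid$mask)

  clim <- build_climatology(truth_f, grid)
  structure(list(truth = truth_f, model = model_f, clim = clim,
                 grid = grid, bias_fn = bias_fn, years = years, seed = seed),
            class = "temperature_world")
}

#' Default synthetic hindcast bias: about +2 C across the shelf
#'
#' Spatially varying warm bias emulating a persistent shelf-wide model
#' bias of around 2 C, modulated weakly by latitude and season.
#'
#' @param lat,lon coordinates (degrees); `month` calendar month.
#' @return Bias in degrees C.
#' @export
default_bias_fn <- function(lat, lon, month) {
  2 + 0.4 * sin(pi * (lat - 37) / 4.5) + 0.2 * cos(2 * pi * month / 12)
}

# Exact decadal-monthly climatologies of a truth field, depth-resolved on
# the coarse grid. Bottom temperature sits at the deepest valid level.
build_climatology <- function(truth, grid) {
  labels <- c("1985-1994", "1995-2004", "2005-2012")
  out <- list()
  depth_clim <- bin_to_clim(grid$depth, grid)
  levels <- standard_levels(max(depth_clim, na.rm = TRUE))
  for (lab in labels) {
    yrs <- intersect(decade_years(lab), unique(truth$time$year))
    if (!length(yrs)) next
    nlat <- length(grid$lat_clim); nlon <- length(grid$lon_clim)
    arr <- array(NA_real_, c(12L, length(levels), nlat, nlon))
    mask_c <- !is.na(depth_clim)
    bottom_lev <- matrix(NA_integer_, nlat, nlon)
    bottom_lev[mask_c] <- findInterval(depth_clim[mask_c], levels)
    for (m in 1:12) {
      idx <- which(truth$time$month == m & truth$time$year %in% yrs)
      dec_mean <- apply(truth$temp[idx, , , drop = FALSE], c(2, 3), mean)
      bottom <- bin_to_clim(dec_mean, grid)
      # deepest valid level carries the bottom value; shallower levels hold
      # a mildly warmer synthetic profile (only the deepest is used downstream)
      for (l in seq_along(levels)) {
        sel <- mask_c & !is.na(bottom) & bottom_lev >= l
        if (!any(sel)) next
        zb <- matrix(levels[pmax(bottom_lev, 1L)], nlat, nlon)
        val <- bottom + 0.05 * (zb - levels[l])
        sl <- arr[m, l, , ]
        sl[sel] <- val[sel]
        arr[m, l, , ] <- sl
      }
    }
    mask_valid <- apply(!is.na(arr), c(3, 4), any)
    out[[lab]] <- climatology_field(lab, grid$lat_clim, grid$lon_clim,
                                    levels, arr, mask_valid)
  }
  out
}

# Bin-average a model-grid matrix onto the climatology grid (NA-aware).
bin_to_clim <- function(mat, grid) {
  lat_edges <- c(grid$lat_clim - grid$res_clim / 2, max(grid$lat_clim) + grid$res_clim / 2)
  lon_edges <- c(grid$lon_clim - grid$res_clim / 2, max(grid$lon_clim) + grid$res_clim / 2)
  ilat <- findInterval(grid$lat_model, lat_edges, rightmost.closed = TRUE)
  ilon <- findInterval(grid$lon_model, lon_edges, rightmost.closed = TRUE)
  nlat <- length(grid$lat_clim); nlon <- length(grid$lon_clim)
  nlat_m <- length(grid$lat_model); nlon_m <- length(grid$lon_model)
  idx <- matrix(ilat, nlat_m, nlon_m) +
    (matrix(ilon, nlat_m, nlon_m, byrow = TRUE) - 1L) * nlat
  inside <- matrix(ilat >= 1 & ilat <= nlat, nlat_m, nlon_m) &
    matrix(ilon >= 1 & ilon <= nlon, nlat_m, nlon_m, byrow = TRUE)
  ok <- !is.na(mat) & inside
  sums <- rowsum(mat[ok], idx[ok])
  cnts <- rowsum(rep(1, sum(ok)), idx[ok])
  out <- matrix(NA_real_, nlat, nlon)
  out[as.integer(rownames(sums))] <- sums / cnts
  out
}

#' @export
print.temperature_world <- function(x, ...) {
  cat(sprintf("temperature_world: years %d-%d, model grid %dx%d, %d climatology decade(s)\n",
              min(x$years), max(x$years), length(x$grid$lat_model),
              length(x$grid$lon_model), length(x$clim)))
  invisible(x)
}
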