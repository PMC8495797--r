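#' Monthly grid on the climatology lattice
#'
#' Lightweight container for a 12-month stack of lat/lon grids, the
#' common currency of the bias-correction step (climatology bottom
#' temperatures, decadal model means and their difference).
#'
#' @param lat,lon grid centres, strictly increasing.
#' @param temp numeric array `(12, length(lat), length(lon))`.
#' @param decade optional decade label carried along.
#' @return An object of class `monthly_grid`.
#' @export
monthly_grid <- function(lat, lon, temp, decade = NULL) {
  stopifnot(all(diff(lat) > 0), all(diff(lon) > 0),
            all(dim(temp) == c(12L, length(lat), length(lon))))
  structure(list(lat = lat, lon = lon, temp = temp, decade = decade),
            class = "monthly_grid")
}

#' Extract bottom temperature from a depth-resolved climatology
#'
#' Bottom temperature is defined as the temperature at the deepest level
#' carrying data in each cell and month. Cells with no valid level stay
#' missing (never zero-filled).
#'
#' @param clim a [climatology_field()].
#' @return A [monthly_grid()] of bottom temperatures.
#' @export
climatology_bottom <- function(clim) {
  stopifnot(inherits(clim, "climatology_field"))
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  out <- array(NA_real_, c(12L, nlat, nlon))
  for (m in 1:12) {
    sl <- clim$temp[m, , , , drop = TRUE]        # (level, lat, lon)
    dim(sl) <- c(length(clim$levels), nlat * nlon)
    # deepest valid level per cell
    deepest <- apply(sl, 2, function(col) {
      i <- which(!is.na(col))
      if (length(i)) col[max(i)] else NA_real_
    })
    out[m, , ] <- matrix(deepest, nlat, nlon)
  }
  monthly_grid(clim$lat, clim$lon, out, decade = clim$decade)
}

# Years belonging to a decadal climatology label.
decade_years <- function(label) {
  switch(label,
         "1985-1994" = 1985:1994,
         "1995-2004" = 1995:2004,
         "2005-2012" = 2005:2012,
         stop(sprintf("unknown decade label '%s'", label)))
}

#' Assign a year to its bias-correction decade
#'
#' Decades follow the available decadal climatologies: 1985-1994,
#' 1995-2004 and 2005-2012, with the last applied to all years through
#' 2015. Years outside 1985-2015 are an error.
#'
#' @param year integer year(s) in 1985-2015.
#' @return Decade label(s).
#' @export
assign_decade <- function(year) {
  if (any(year < 1985 | year > 2015))
    stop("year outside the 1985-2015 coverage")
  ifelse(year <= 1994, "1985-1994",
         ifelse(year <= 2004, "1995-2004", "2005-2012"))
}

#' Decadal monthly mean of a model field, binned to the climatology grid
#'
#' Averages the model field's monthly bottom temperatures over the years
#' of a decade, then bin-averages (not interpolates) the model cells
#' falling inside each climatology cell. Climatology cells receiving no
#' wet model cell stay missing.
#'
#' @param model a [grid_field()].
#' @param decade decade label (see [assign_decade()]).
#' @param clim_grid a [climatology_field()] or [monthly_grid()] supplying
#'   the target lattice.
#' @return A [monthly_grid()] on the climatology lattice.
#' @export
decadal_monthly_mean_regrid <- function(model, decade, clim_grid) {
  stopifnot(inherits(model, "grid_field"))
  yrs <- intersect(decade_years(decade), unique(model$time$year))
  if (!length(yrs))
    stop(sprintf("model field has no years overlapping decade %s", decade))
  lat_c <- clim_grid$lat; lon_c <- clim_grid$lon
  res_lat <- if (length(lat_c) > 1) lat_c[2] - lat_c[1] else 0.1
  res_lon <- if (length(lon_c) > 1) lon_c[2] - lon_c[1] else 0.1
  lat_edges <- c(lat_c - res_lat / 2, max(lat_c) + res_lat / 2)
  lon_edges <- c(lon_c - res_lon / 2, max(lon_c) + res_lon / 2)
  ilat <- findInterval(model$lat, lat_edges, rightmost.closed = TRUE)
  ilon <- findInterval(model$lon, lon_edges, rightmost.closed = TRUE)
  nlat_c <- length(lat_c); nlon_c <- length(lon_c)
  nlat_m <- length(model$lat); nlon_m <- length(model$lon)
  cellmap <- matrix(ilat, nlat_m, nlon_m) +
    (matrix(ilon, nlat_m, nlon_m, byrow = TRUE) - 1L) * nlat_c
  inside <- matrix(ilat >= 1 & ilat <= nlat_c, nlat_m, nlon_m) &
    matrix(ilon >= 1 & ilon <= nlon_c, nlat_m, nlon_m, byrow = TRUE)

  out <- array(NA_real_, c(12L, nlat_c, nlon_c))
  for (m in 1:12) {
    idx <- which(model$time$month == m & model$time$year %in% yrs)
    if (!length(idx)) next
    dec_mean <- apply(model$temp[idx, , , drop = FALSE], c(2, 3), mean)
    ok <- inside & !is.na(dec_mean)
    if (!any(ok)) next
    sums <- rowsum(dec_mean[ok], cellmap[ok])
    cnts <- rowsum(rep(1, sum(ok)), cellmap[ok])
    sl <- matrix(NA_real_, nlat_c, nlon_c)
    sl[as.integer(rownames(sums))] <- sums / cnts
    out[m, , ] <- sl
  }
  monthly_grid(lat_c, lon_c, out, decade = decade)
}

#' Spatially varying bias: model decadal mean minus climatology
#'
#' @param model_decadal a [monthly_grid()] from
#'   [decadal_monthly_mean_regrid()].
#' @param clim_bottom a [monthly_grid()] from [climatology_bottom()].
#' @return A [monthly_grid()] of biases (degrees C), missing wherever
#'   either input is missing.
#' @export
compute_bias_field <- function(model_decadal, clim_bottom) {
  stopifnot(inherits(model_decadal, "monthly_grid"),
            inherits(clim_bottom, "monthly_grid"))
  if (!isTRUE(all.equal(model_decadal$lat, clim_bottom$lat)) ||
      !isTRUE(all.equal(model_decadal$lon, clim_bottom$lon)))
    stop("grid mismatch between model decadal mean and climatology")
  monthly_grid(clim_bottom$lat, clim_bottom$lon,
               model_decadal$temp - clim_bottom$temp,
               decade = model_decadal$decade %||% clim_bottom$decade)
}

#' Apply decadal monthly bias fields to a model temperature stack
#'
#' Each model time slice is corrected by subtracting, at every wet model
#' cell, the bias of the nearest climatology cell for the slice's month
#' and decade. The model grid and wet mask are retained. Model cells
#' whose nearest climatology cell carries no bias fall back to the
#' nearest valid climatology cell within 0.5 degrees; cells with no such
#' neighbour are set missing and counted in the `n_dropped` attribute.
#'
#' @param model a [grid_field()].
#' @param biases named list of [monthly_grid()] bias fields keyed by
#'   decade label; every decade required by the model's years must be
#'   present.
#' @return A corrected [grid_field()] with attribute `n_dropped`.
#' @export
apply_bias <- function(model, biases) {
  stopifnot(inherits(model, "grid_field"))
  decades_needed <- unique(assign_decade(model$time$year))
  missing_dec <- setdiff(decades_needed, names(biases))
  if (length(missing_dec))
    stop(sprintf("missing bias field for decade(s): %s",
                 paste(missing_dec, collapse = ", ")))
  b1 <- biases[[1]]
  nlat_m <- length(model$lat); nlon_m <- length(model$lon)
  near_lat <- vapply(model$lat, function(x) which.min(abs(b1$lat - x)), integer(1))
  near_lon <- vapply(model$lon, function(x) which.min(abs(b1$lon - x)), integer(1))
  map_idx <- matrix(near_lat, nlat_m, nlon_m) +
    (matrix(near_lon, nlat_m, nlon_m, byrow = TRUE) - 1L) * length(b1$lat)

  corrected <- model$temp
  n_dropped <- 0L
  for (i in seq_len(nrow(model$time))) {
    dec <- assign_decade(model$time$year[i])
    m <- model$time$month[i]
    bias_sl <- biases[[dec]]$temp[m, , ]
    bvals <- bias_sl[map_idx]
    dim(bvals) <- c(nlat_m, nlon_m)
    need_fb <- model$mask & is.na(bvals)
    if (any(need_fb)) {
      valid <- which(!is.na(bias_sl), arr.ind = TRUE)
      for (cell in which(need_fb)) {
        il <- (cell - 1L) %% nlat_m + 1L; io <- (cell - 1L) %/% nlat_m + 1L
        dlat <- b1$lat[valid[, 1]] - model$lat[il]
        dlon <- b1$lon[valid[, 2]] - model$lon[io]
        ok <- abs(dlat) <= 0.5 & abs(dlon) <= 0.5
        if (any(ok)) {
          d2 <- dlat[ok]^2 + dlon[ok]^2
          j <- which(ok)[which.min(d2)]
          bvals[cell] <- bias_sl[valid[j, 1], valid[j, 2]]
        } else {
          n_dropped <- n_dropped + 1L
        }
      }
    }
    sl <- model$temp[i, , ] - bvals
    sl[!model$mask] <- NA_real_
    corrected[i, , ] <- sl
  }
  if (n_dropped > 0)
    message(sprintf("apply_bias: %d wet cell-months had no bias within 0.5 deg and were set missing",
                    n_dropped))
  out <- grid_field(model$lat, model$lon, model$time, corrected, model$mask)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Match tows to the nearest corrected monthly bottom temperature
#'
#' Each tow is paired with the bias-corrected temperature of the nearest
#' wet model cell (great-circle distance) for the tow's year and month.
#' Equidistant candidates break ties deterministically toward the lowest
#' flattened cell index (latitude index varying fastest). Tows with no
#' wet cell within `cutoff_km` get a missing value; their count is
#' reported in the `n_unmatched` attribute and a message.
#'
#' @param tows data.frame with columns `year`, `month`, `lat`, `lon`.
#' @param corrected a [grid_field()] of corrected temperatures.
#' @param cutoff_km maximum match radius, km (default 25).
#' @return Numeric vector of matched temperatures (degrees C) with
#'   attribute `n_unmatched`.
#' @export
match_trawls <- function(tows, corrected, cutoff_km = 25) {
  stopifnot(inherits(corrected, "grid_field"),
            all(c("year", "month", "lat", "lon") %in% names(tows)))
  ti <- time_index(corrected, tows$year, tows$month)
  if (any(is.na(ti)))
    stop("tow date outside the corrected field's coverage")
  nlat <- length(corrected$lat); nlon <- length(corrected$lon)
  wet <- which(corrected$mask)
  wet_il <- (wet - 1L) %% nlat + 1L
  wet_io <- (wet - 1L) %/% nlat + 1L
  wet_lat <- corrected$lat[wet_il]
  wet_lon <- corrected$lon[wet_io]
  # candidate box: cutoff padded by one cell, in degrees
  res_lat <- if (nlat > 1) corrected$lat[2] - corrected$lat[1] else 1
  pad_lat <- cutoff_km / 110.574 + res_lat
  out <- rep(NA_real_, nrow(tows))
  n_unmatched <- 0L
  for (i in seq_len(nrow(tows))) {
    pad_lon <- cutoff_km / (111.32 * cos(tows$lat[i] * pi / 180)) + res_lat
    cand <- which(abs(wet_lat - tows$lat[i]) <= pad_lat &
                    abs(wet_lon - tows$lon[i]) <= pad_lon)
    if (!length(cand)) cand <- seq_along(wet)
    d <- geosphere::distHaversine(cbind(tows$lon[i], tows$lat[i]),
                                  cbind(wet_lon[cand], wet_lat[cand])) / 1000
    ord <- order(d, wet[cand])
    best <- ord[1]
    if (d[best] > cutoff_km) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    out[i] <- corrected$temp[ti[i] + (wet[cand][best] - 1L) * nrow(corrected$time)]
  }
  if (n_unmatched > 0)
    message(sprintf("match_trawls: %d tow(s) had no wet cell within %.0f km and were left unmatched",
                    n_unmatched, cutoff_km))
  attr(out, "n_unmatched") <- n_unmatched
  out
}
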