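#' Seasonal mean of a corrected temperature field
#'
#' Cellwise mean over the season's months (spring = March-May, fall =
#' September-November) across a range of years.
#'
#' @param corrected a [grid_field()].
#' @param season `"spring"`, `"fall"`, or an integer vector of months.
#' @param years years to average over (default: all covered).
#' @return List of class `temp_grid` with `lat`, `lon`, `temp` (matrix),
#'   `season`, `years`.
#' @export
seasonal_mean <- function(corrected, season = c("spring", "fall"),
                          years = NULL) {
  stopifnot(inherits(corrected, "grid_field"))
  if (is.character(season)) {
    season <- match.arg(season)
    months <- if (season == "spring") 3:5 else 9:11
  } else {
    months <- as.integer(season)
    season <- paste(months, collapse = ",")
  }
  years <- years %||% unique(corrected$time$year)
  idx <- which(corrected$time$month %in% months & corrected$time$year %in% years)
  if (!length(idx)) stop("field does not cover the requested months/years")
  temp <- apply(corrected$temp[idx, , , drop = FALSE], c(2, 3), mean)
  structure(list(lat = corrected$lat, lon = corrected$lon, temp = temp,
                 season = season, years = sort(unique(corrected$time$year[idx]))),
            class = "temp_grid")
}

#' Project a thermal response curve onto a temperature grid
#'
#' Habitat quality per cell is the curve's scaled (0-1) response at the
#' cell's temperature. Temperatures outside 0-30 C are clamped to the
#' scaling range, with the clamped-cell count reported.
#'
#' @param curve a [thermal_curve()].
#' @param temp_grid a `temp_grid` from [seasonal_mean()].
#' @param label curve label carried into the map.
#' @return List of class `habitat_map` with `lat`, `lon`, `quality`
#'   matrix in `[0, 1]` (missing on dry cells), `season`, `source`, and
#'   attribute `n_clamped`.
#' @export
project_habitat <- function(curve, temp_grid, label = NULL) {
  stopifnot(inherits(curve, "thermal_curve"), inherits(temp_grid, "temp_grid"))
  sf <- scale_response(curve)
  temp <- temp_grid$temp
  wet <- !is.na(temp)
  n_clamped <- sum(temp[wet] < 0 | temp[wet] > 30)
  if (n_clamped > 0)
    message(sprintf("project_habitat: %d cell(s) outside 0-30 C clamped", n_clamped))
  quality <- matrix(NA_real_, nrow(temp), ncol(temp))
  quality[wet] <- sf(pmin(pmax(temp[wet], 0), 30))
  out <- structure(list(lat = temp_grid$lat, lon = temp_grid$lon,
                        quality = quality, season = temp_grid$season,
                        source = label %||% paste(unlist(curve$fitted_on),
                                                  collapse = " / ")),
                   class = "habitat_map")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' @export
print.habitat_map <- function(x, ...) {
  q <- x$quality[!is.na(x$quality)]
  cat(sprintf("habitat_map (%s, %s): %d wet cells, quality %.2f-%.2f (mean %.2f)\n",
              x$source, x$season, length(q), min(q), max(q), mean(q)))
  invisible(x)
}
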