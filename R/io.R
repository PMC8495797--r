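# Readers/writers for the pipeline's on-disk artifacts. All formats are
# plain text: trawl and curve tables as CSV, gridded fields as
# long-format CSV carrying the (year, month, lat, lon) dimensions and a
# wet/dry mask column, descriptors as JSON sidecars. Numeric values are
# written with 17 significant digits so a write/read round trip
# reproduces the doubles exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

trawl_cols <- c("survey", "year", "month", "day", "lat", "lon",
                "depth_m", "temp_insitu_c", "presence")

#' Write trawl records to CSV
#'
#' Columns are exactly `survey, year, month, day, lat, lon, depth_m,
#' temp_insitu_c, presence`, plus `temp_model_c` when matched model
#' temperatures are present. Missing in situ temperatures are written as
#' empty fields.
#'
#' @param tows trawl data.frame.
#' @param path output file.
#' @export
write_trawls <- function(tows, path) {
  cols <- c(trawl_cols, intersect("temp_model_c", names(tows)))
  missing <- setdiff(trawl_cols, names(tows))
  if (length(missing))
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  out <- tows[, cols]
  out$presence <- as.integer(as.logical(out$presence))
  for (cc in intersect(c("lat", "lon", "depth_m", "temp_insitu_c", "temp_model_c"),
                       cols))
    out[[cc]] <- fmt_num(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate trawl records from CSV
#'
#' Rows violating the record invariants (month outside 1-12, depth not
#' positive, non-finite in situ temperature, presence not 0/1) are
#' rejected with a line-numbered message; missing in situ temperature is
#' allowed (observer-like sources carry none).
#'
#' @param path CSV file with the documented header.
#' @return Validated trawl data.frame with logical `presence`.
#' @export
read_trawls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trawl_cols, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  df$temp_insitu_c <- as.numeric(df$temp_insitu_c)
  bad <- with(df,
              is.na(month) | month < 1 | month > 12 |
                is.na(depth_m) | depth_m <= 0 |
                (!is.na(temp_insitu_c) & !is.finite(temp_insitu_c)) |
                is.na(presence) | !(presence %in% c(0, 1)))
  if (any(bad)) {
    # +1 for the header line
    message(sprintf("read_trawls: rejected %d invalid row(s) at line(s) %s",
                    sum(bad), paste(utils::head(which(bad) + 1L, 20), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  df$presence <- as.logical(df$presence)
  df
}

#' Write a gridded field to long-format CSV
#'
#' One row per (year, month, lat, lon) cell with columns `temp` and
#' `mask`; climatology fields add `decade` and `depth_m` columns and use
#' `decade` in place of `year`.
#'
#' @param field a [grid_field()] or [climatology_field()].
#' @param path output file.
#' @export
write_grid_file <- function(field, path) {
  if (inherits(field, "grid_field")) {
    nt <- nrow(field$time)
    nlat <- length(field$lat); nlon <- length(field$lon)
    df <- data.frame(
      year = rep(field$time$year, nlat * nlon),
      month = rep(field$time$month, nlat * nlon),
      lat = rep(rep(field$lat, each = nt), nlon),
      lon = rep(field$lon, each = nt * nlat),
      temp = fmt_num(as.vector(field$temp)),
      mask = as.integer(rep(as.vector(field$mask), each = nt)))
    df$lat <- fmt_num(df$lat); df$lon <- fmt_num(df$lon)
  } else if (inherits(field, "climatology_field")) {
    nlev <- length(field$levels)
    nlat <- length(field$lat); nlon <- length(field$lon)
    df <- data.frame(
      decade = field$decade,
      month = rep(1:12, nlev * nlat * nlon),
      depth_m = rep(rep(field$levels, each = 12L), nlat * nlon),
      lat = rep(rep(field$lat, each = 12L * nlev), nlon),
      lon = rep(field$lon, each = 12L * nlev * nlat),
      temp = fmt_num(as.vector(field$temp)),
      mask = as.integer(rep(as.vector(field$mask), each = 12L * nlev)))
    df$lat <- fmt_num(df$lat); df$lon <- fmt_num(df$lon)
  } else stop("field must be a grid_field or climatology_field")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a gridded field from long-format CSV
#'
#' Dispatches on the columns present: a `depth_m` + `decade` pair yields
#' a [climatology_field()] (with the 5/25/50 m level scheme validated by
#' its constructor), otherwise a [grid_field()]. A file lacking the
#' `mask` column is assumed all-wet with a warning.
#'
#' @param path CSV file written by [write_grid_file()].
#' @return A [grid_field()] or [climatology_field()].
#' @export
read_grid_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  is_clim <- all(c("decade", "depth_m") %in% names(df))
  req <- c(if (is_clim) c("decade", "depth_m") else "year",
           "month", "lat", "lon", "temp")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop(sprintf("grid file lacks dimension column(s): %s",
                 paste(missing, collapse = ", ")))
  df$lat <- as.numeric(df$lat); df$lon <- as.numeric(df$lon)
  df$temp <- as.numeric(df$temp)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  if (!"mask" %in% names(df)) {
    warning("grid file has no mask variable; assuming all cells wet")
    df$mask <- 1L
  }
  if (is_clim) {
    levels <- sort(unique(as.numeric(df$depth_m)))
    o <- order(df$lon, df$lat, df$depth_m, df$month)
    temp <- array(df$temp[o], c(12L, length(levels), length(lat), length(lon)))
    mask <- matrix(df$mask[o][seq(1, nrow(df), by = 12L * length(levels))] > 0,
                   length(lat), length(lon))
    climatology_field(df$decade[1], lat, lon, levels, temp, mask)
  } else {
    time <- unique(df[, c("year", "month")])
    time <- time[order(time$year, time$month), ]
    nt <- nrow(time)
    o <- order(df$lon, df$lat, df$year, df$month)
    temp <- array(df$temp[o], c(nt, length(lat), length(lon)))
    mask <- matrix(df$mask[o][seq(1, nrow(df), by = nt)] > 0,
                   length(lat), length(lon))
    grid_field(lat, lon, time, temp, mask)
  }
}

#' Write a fitted curve and its descriptors
#'
#' The curve goes to CSV (columns `t, linear_predictor, se, response,
#' scaled_response`); the descriptors to a JSON sidecar alongside it.
#'
#' @param curve a [thermal_curve()].
#' @param path CSV output file; the sidecar replaces the extension with
#'   `.json`.
#' @export
write_curve <- function(curve, path) {
  sf <- tryCatch(scale_response(curve), error = function(e) NULL)
  resp <- if (curve$family == "binomial_logit") stats::plogis(curve$lp) else
    exp(curve$lp)
  df <- data.frame(t = fmt_num(curve$t_grid),
                   linear_predictor = fmt_num(curve$lp),
                   se = fmt_num(curve$se),
                   response = fmt_num(resp),
                   scaled_response = fmt_num(
                     if (is.null(sf)) rep(NA_real_, length(curve$t_grid))
                     else sf(curve$t_grid)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  desc <- suppressWarnings(curve_descriptors(curve))
  side <- list(family = curve$family,
               deviance_explained = curve$deviance_explained,
               data_range = curve$data_range,
               fitted_on = curve$fitted_on,
               t_opt = desc$t_opt,
               positive_range = desc$positive_range,
               open_low = desc$open_low, open_high = desc$open_high,
               unimodal = desc$unimodal, extrapolated = desc$extrapolated)
  jsonlite::write_json(side, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write cross-validation results as long-format CSV
#'
#' @param cv a `cv_result`.
#' @param path output file.
#' @export
write_cv_result <- function(cv, path) {
  df <- data.frame(scheme = cv$scheme,
                   iteration = seq_along(cv$auc),
                   auc = cv$auc,
                   n_train = cv$n_train, n_test = cv$n_test)
  if (!is.null(cv$blocks)) {
    df$block_start <- cv$blocks$start
    df$block_end <- cv$blocks$end
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a habitat map as long-format CSV
#'
#' @param map a `habitat_map`.
#' @param path output file.
#' @export
write_habitat_map <- function(map, path) {
  df <- data.frame(lat = rep(map$lat, length(map$lon)),
                   lon = rep(map$lon, each = length(map$lat)),
                   quality = as.vector(map$quality))
  df$season <- map$season; df$source <- map$source
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
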