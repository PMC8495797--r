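#' Fitted thermal response curve
#'
#' Container for a smooth response of presence (log-odds) or aerobic
#' scope (log-rate) to bottom temperature, evaluated with pointwise
#' standard errors on a fixed 0-30 C grid (0.1 C step) so curves from
#' different data sources and model families are directly comparable.
#' Downstream consumers (descriptors, scaling, ranking, projection) work
#' from the stored grid by linear interpolation, so a curve may come from
#' an mgcv fit or be constructed analytically.
#'
#' @param t_grid evaluation grid, degrees C.
#' @param lp linear predictor (log-odds or log-rate) on `t_grid`.
#' @param se pointwise standard error of `lp`.
#' @param family `"binomial_logit"` or `"poisson_log"`.
#' @param deviance_explained fraction in `[0, 1]`.
#' @param data_range temperature range actually sampled by the training
#'   data; predictions outside it are extrapolations.
#' @param fitted_on optional labels (data source, temperature source).
#' @param model optional underlying `mgcv::gam` fit.
#' @return An object of class `thermal_curve`.
#' @export
thermal_curve <- function(t_grid, lp, se = rep(NA_real_, length(t_grid)),
                          family = c("binomial_logit", "poisson_log"),
                          deviance_explained = NA_real_,
                          data_range = range(t_grid),
                          fitted_on = NULL, model = NULL) {
  family <- match.arg(family)
  stopifnot(length(lp) == length(t_grid), length(se) == length(t_grid))
  if (any(!is.finite(lp))) stop("linear predictor must be finite on the grid")
  structure(list(t_grid = t_grid, lp = lp, se = se, family = family,
                 deviance_explained = deviance_explained,
                 data_range = data_range, fitted_on = fitted_on,
                 model = model),
            class = "thermal_curve")
}

response_grid <- function(step = 0.1) seq(0, 30, by = step)

# Link-scale prediction at arbitrary temperatures by linear interpolation
# on the stored grid (clamped at the grid ends).
curve_lp <- function(curve, t) {
  stats::approx(curve$t_grid, curve$lp, xout = pmin(pmax(t, min(curve$t_grid)),
                                                    max(curve$t_grid)))$y
}

# Response-scale prediction (probability or rate).
curve_response <- function(curve, t) {
  lp <- curve_lp(curve, t)
  if (curve$family == "binomial_logit") stats::plogis(lp) else exp(lp)
}

#' Predict from a thermal curve
#'
#' @param object a [thermal_curve()].
#' @param t temperatures, degrees C.
#' @param type `"link"` (log-odds / log-rate) or `"response"`
#'   (probability / rate).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.thermal_curve <- function(object, t, type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (type == "link") curve_lp(object, t) else curve_response(object, t)
}

#' @export
print.thermal_curve <- function(x, ...) {
  cat(sprintf("thermal_curve (%s): deviance explained %.1f%%, data range %.1f-%.1f C\n",
              x$family, 100 * x$deviance_explained,
              x$data_range[1], x$data_range[2]))
  invisible(x)
}

#' Fit a presence-absence thermal response curve
#'
#' Penalized univariate spline smoother of presence on temperature, on
#' the logit scale, using a thin plate regression spline whose penalty is
#' modified to also shrink the null space (`mgcv` basis `"ts"`), so an
#' uninformative smooth can shrink toward a flat line rather than retain
#' a spurious linear trend. The smoothing parameter is selected by REML.
#' The null-space penalty also keeps estimates finite under complete
#' separation.
#'
#' @param temps tow temperatures, degrees C (finite).
#' @param presence logical (or 0/1) presence flags.
#' @param k spline basis dimension (default 10).
#' @param sp optional fixed smoothing parameter overriding REML
#'   selection.
#' @param fitted_on optional labels carried into the curve.
#' @return A [thermal_curve()] with family `"binomial_logit"`.
#' @export
fit_presence_curve <- function(temps, presence, k = 10, sp = NULL,
                               fitted_on = NULL) {
  if (any(!is.finite(temps))) stop("non-finite temperatures")
  presence <- as.logical(presence)
  if (length(temps) != length(presence)) stop("length mismatch")
  if (all(presence) || all(!presence))
    stop("degenerate response: all outcomes identical")
  dat <- data.frame(t = temps, y = as.integer(presence))
  fit <- mgcv::gam(y ~ s(t, k = k, bs = "ts"), data = dat,
                   family = stats::binomial(), method = "REML",
                   sp = if (is.null(sp)) NULL else sp)
  curve_from_gam(fit, temps, "binomial_logit", fitted_on)
}

#' Fit a laboratory aerobic-scope thermal performance curve
#'
#' Log-link smooth of aerobic scope on temperature with a small basis
#' (default dimension 3), fitted with a quasi-Poisson family so the
#' Poisson mean-variance structure applies to continuous scope values
#' without integer rounding.
#'
#' @param lab data.frame with columns `temp_c` and `scope` (>= 0).
#' @param k spline basis dimension (default 3).
#' @param sp optional fixed smoothing parameter (alternative reading of a
#'   "smoothing factor": pass `sp = 3` to fix the penalty instead).
#' @param fitted_on optional labels carried into the curve.
#' @return A [thermal_curve()] with family `"poisson_log"`.
#' @export
fit_scope_curve <- function(lab, k = 3, sp = NULL, fitted_on = NULL) {
  stopifnot(all(c("temp_c", "scope") %in% names(lab)))
  if (any(lab$scope < 0)) stop("negative scope values")
  if (length(unique(lab$temp_c)) < 3)
    stop("need at least 3 distinct temperatures")
  if (stats::sd(lab$scope) == 0) {
    # constant scope: REML has nothing to estimate; the curve is exactly flat
    if (mean(lab$scope) <= 0) stop("scope values are all zero")
    grid <- response_grid()
    return(thermal_curve(grid, rep(log(mean(lab$scope)), length(grid)),
                         rep(0, length(grid)), family = "poisson_log",
                         deviance_explained = 0,
                         data_range = range(lab$temp_c), fitted_on = fitted_on))
  }
  fit <- mgcv::gam(scope ~ s(temp_c, k = k, bs = "ts"), data = lab,
                   family = stats::quasipoisson(), method = "REML",
                   sp = if (is.null(sp)) NULL else sp)
  curve_from_gam(fit, lab$temp_c, "poisson_log", fitted_on,
                 term = "temp_c")
}

curve_from_gam <- function(fit, temps, family, fitted_on, term = "t") {
  grid <- response_grid()
  nd <- stats::setNames(data.frame(grid), term)
  pr <- mgcv::predict.gam(fit, newdata = nd, type = "link", se.fit = TRUE)
  dev_expl <- 1 - fit$deviance / fit$null.deviance
  thermal_curve(grid, as.numeric(pr$fit), as.numeric(pr$se.fit),
                family = family, deviance_explained = dev_expl,
                data_range = range(temps), fitted_on = fitted_on,
                model = fit)
}

#' Thermal descriptors of a fitted curve
#'
#' Extracts the positive response range (the widest connected
#' temperature interval where the linear predictor exceeds zero, i.e.
#' predicted presence probability above 0.5, with endpoints linearly
#' interpolated between grid points) and the thermal optimum, defined
#' only for curves showing a steady increase followed by a steady
#' decrease over the sampled temperature range. The steadiness test
#' tolerates wiggles whose cumulative magnitude is below 5% of the
#' curve's total variation, so a mildly bimodal but clearly peaked curve
#' still reports its global argmax as the optimum. Descriptors are
#' computed over the full 0-30 C grid; `extrapolated` flags whether any
#' reported descriptor falls outside the sampled temperature range.
#'
#' @param curve a [thermal_curve()].
#' @param wiggle_tol tolerated fraction of total variation violating
#'   monotonicity on either side of the peak (default 0.05).
#' @return List with elements `t_opt` (degrees C or `NA`),
#'   `positive_range` (length-2 numeric or `NULL`), `open_low`,
#'   `open_high`, `unimodal`, `extrapolated`.
#' @export
curve_descriptors <- function(curve, wiggle_tol = 0.05) {
  stopifnot(inherits(curve, "thermal_curve"))
  tg <- curve$t_grid; lp <- curve$lp

  # unimodality assessed over the sampled temperature range only
  in_range <- tg >= curve$data_range[1] & tg <= curve$data_range[2]
  unimodal <- FALSE
  if (sum(in_range) >= 3) {
    lpr <- lp[in_range]
    d <- diff(lpr)
    tv <- sum(abs(d))
    pk <- which.max(lpr)
    if (tv > 0 && pk > 1 && pk < length(lpr)) {
      viol <- sum(pmax(0, -d[seq_len(pk - 1)])) +
        sum(pmax(0, d[seq(pk, length(d))]))
      # a genuine peak needs a substantial rise before and fall after it:
      # a monotone rise that merely levels off (plateau) has no optimum
      rise <- lpr[pk] - lpr[1]
      fall <- lpr[pk] - lpr[length(lpr)]
      unimodal <- viol < wiggle_tol * tv &&
        rise > wiggle_tol * tv && fall > wiggle_tol * tv
    }
  }
  t_opt <- if (unimodal) tg[which.max(lp)] else NA_real_

  # widest connected run of positive log-odds, endpoints interpolated
  pos <- lp > 0
  positive_range <- NULL
  open_low <- open_high <- FALSE
  if (any(pos)) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    widest <- runs[which.max(r$lengths[runs])]
    i0 <- starts[widest]; i1 <- ends[widest]
    low <- if (i0 == 1) { open_low <- TRUE; tg[1] } else
      tg[i0 - 1] + (tg[i0] - tg[i0 - 1]) * (0 - lp[i0 - 1]) / (lp[i0] - lp[i0 - 1])
    high <- if (i1 == length(tg)) { open_high <- TRUE; tg[length(tg)] } else
      tg[i1] + (tg[i1 + 1] - tg[i1]) * (0 - lp[i1]) / (lp[i1 + 1] - lp[i1])
    positive_range <- c(low, high)
  }

  extrapolated <- FALSE
  if (!is.null(positive_range))
    extrapolated <- positive_range[1] < curve$data_range[1] ||
      positive_range[2] > curve$data_range[2]
  if (!is.na(t_opt))
    extrapolated <- extrapolated || t_opt < curve$data_range[1] ||
      t_opt > curve$data_range[2]
  if (extrapolated)
    warning("descriptors extend beyond the sampled temperature range; interpret with caution")

  list(t_opt = t_opt, positive_range = positive_range,
       open_low = open_low, open_high = open_high,
       unimodal = unimodal, extrapolated = extrapolated)
}

#' Scale a curve's response to [0, 1] over the 0-30 C grid
#'
#' On the response scale (probability or rate), returns the function
#' `(r(t) - r_min) / (r_max - r_min)` with extremes taken over the 0-30 C
#' grid. Presence curves are asymptotic to zero at cold temperatures, so
#' for them this effectively normalizes to the maximum; aerobic scope
#' lives on a much larger scale and needs the full min-max form.
#'
#' @param curve a [thermal_curve()].
#' @param range scaling range, degrees C (default `c(0, 30)`).
#' @return A function `f(t)` returning scaled values in `[0, 1]`
#'   (temperatures outside `range` are clamped), with attributes `r_min`,
#'   `r_max`.
#' @export
scale_response <- function(curve, range = c(0, 30)) {
  stopifnot(inherits(curve, "thermal_curve"))
  keep <- curve$t_grid >= range[1] & curve$t_grid <= range[2]
  tg <- curve$t_grid[keep]
  r <- if (curve$family == "binomial_logit") stats::plogis(curve$lp[keep]) else
    exp(curve$lp[keep])
  r_min <- min(r); r_max <- max(r)
  if (!is.finite(r_max - r_min) || (r_max - r_min) < 1e-12 * max(1, abs(r_max)))
    stop("flat response not scalable")
  f <- function(t) {
    tt <- pmin(pmax(t, min(tg)), max(tg))
    (stats::approx(tg, r, xout = tt)$y - r_min) / (r_max - r_min)
  }
  attr(f, "r_min") <- r_min
  attr(f, "r_max") <- r_max
  f
}
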