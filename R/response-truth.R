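#' True thermal response parameters for the synthetic world
#'
#' Defines the generating presence-probability curve from which synthetic
#' tows draw their presence flags. Two shapes are supported: a dome
#' (rise to a single optimum, then decline — the shape seen in shelf-wide
#' survey and observer curves) and a plateau (monotone rise that levels
#' off, the shape seen in the inshore New Jersey curve).
#'
#' The dome is piecewise Gaussian on the probability scale,
#' \deqn{P(t) = p_{max} \exp\{-(t - t_{opt})^2 / (2\sigma^2_{side})\},}
#' with separate widths left and right of the optimum so the lower and
#' upper limits need not be symmetric. Each width is set from the
#' corresponding limit: when `p_max > 0.5` the limits are placed exactly
#' where the curve crosses probability 0.5, i.e. where the log-odds cross
#' zero, so `t_low`/`t_high` are the true positive-response range and a
#' well-fit presence model should recover them. When `p_max <= 0.5` the
#' log-odds never reach zero anywhere, so no positive range exists; the
#' limits are then interpreted as support edges where the curve has
#' decayed to 10% of its peak.
#'
#' The plateau is \eqn{P(t) = p_{max} \mathrm{plogis}((t - t_{low})/s)}:
#' monotone non-decreasing with asymptote `p_max` and rise midpoint
#' `t_low`.
#'
#' @param shape `"dome"` or `"plateau"`.
#' @param t_opt dome optimum, degrees C (ignored for plateau).
#' @param t_low,t_high lower/upper limits, degrees C. For the plateau only
#'   `t_low` (rise midpoint) is used.
#' @param p_max peak (dome) or asymptotic (plateau) presence probability,
#'   in (0, 1].
#' @param rise_scale plateau logistic rise scale, degrees C.
#' @return An object of class `true_response` holding the parameters and
#'   derived widths.
#' @seealso [eval_true_response()], [true_positive_range()]
#' @export
true_response_params <- function(shape = c("dome", "plateau"),
                                 t_opt = 18, t_low = 8.5, t_high = 26.5,
                                 p_max = 0.5, rise_scale = 2) {
  shape <- match.arg(shape)
  if (!is.finite(p_max) || p_max <= 0 || p_max > 1)
    stop("p_max must lie in (0, 1]")
  if (shape == "dome") {
    if (!(t_low < t_opt && t_opt < t_high))
      stop("dome requires t_low < t_opt < t_high")
    p_edge <- if (p_max > 0.5) 0.5 else 0.1 * p_max
    sigma_l <- (t_opt - t_low) / sqrt(2 * log(p_max / p_edge))
    sigma_r <- (t_high - t_opt) / sqrt(2 * log(p_max / p_edge))
    out <- list(shape = shape, t_opt = t_opt, t_low = t_low, t_high = t_high,
                p_max = p_max, p_edge = p_edge,
                sigma_l = sigma_l, sigma_r = sigma_r)
  } else {
    out <- list(shape = shape, t_low = t_low, p_max = p_max,
                rise_scale = rise_scale)
  }
  structure(out, class = "true_response")
}

#' Evaluate the true presence probability at given temperatures
#'
#' @param params a [true_response_params()] object.
#' @param t temperature(s), degrees C; must be finite.
#' @return Presence probabilities in `[0, p_max]`, same length as `t`.
#' @export
eval_true_response <- function(params, t) {
  stopifnot(inherits(params, "true_response"))
  if (any(!is.finite(t))) stop("temperatures must be finite")
  if (params$shape == "dome") {
    sigma <- ifelse(t <= params$t_opt, params$sigma_l, params$sigma_r)
    params$p_max * exp(-(t - params$t_opt)^2 / (2 * sigma^2))
  } else {
    params$p_max * stats::plogis((t - params$t_low) / params$rise_scale)
  }
}

#' True positive-response range of a generating curve
#'
#' The temperature interval over which the true log-odds exceed zero
#' (presence probability above 0.5). Only defined when `p_max > 0.5`.
#'
#' @param params a [true_response_params()] object.
#' @return Numeric length-2 vector (upper may be `Inf` for a plateau), or
#'   `NULL` when the curve never exceeds probability 0.5.
#' @export
true_positive_range <- function(params) {
  stopifnot(inherits(params, "true_response"))
  if (params$p_max <= 0.5) return(NULL)
  if (params$shape == "dome") {
    # limits were constructed as the exact 0.5 crossings
    c(params$t_low, params$t_high)
  } else {
    q <- 0.5 / params$p_max
    c(params$t_low + params$rise_scale * log(q / (1 - q)), Inf)
  }
}

#' @export
print.true_response <- function(x, ...) {
  if (x$shape == "dome")
    cat(sprintf("true dome response: Topt %.1f C, limits %.1f-%.1f C, peak P %.2f\n",
                x$t_opt, x$t_low, x$t_high, x$p_max))
  else
    cat(sprintf("true plateau response: rise midpoint %.1f C, asymptote P %.2f\n",
                x$t_low, x$p_max))
  invisible(x)
}
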