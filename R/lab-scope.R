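#' Generate laboratory aerobic-scope measurements
#'
#' Emulates a respirometry study design: a fixed number of fish measured
#' at each of five test temperatures between 12 and 30 C, with aerobic
#' scope (maximum minus standard metabolic rate, arbitrary O2 units)
#' drawn around a dome-shaped thermal performance curve peaking at
#' `t_opt_lab`. Noise is multiplicative (log-normal), as metabolic-rate
#' scatter scales with its level.
#'
#' @param t_opt_lab peak of the true performance curve, degrees C
#'   (default 24.8, a few degrees above typical field optima).
#' @param n_per_temp fish per test temperature (10-12 in the emulated
#'   design; any positive count accepted).
#' @param temps five (or more) strictly increasing test temperatures
#'   within `[12, 30]`.
#' @param seed integer seed.
#' @param noise_cv log-scale sd of the multiplicative noise (0 = none).
#' @param scope_max peak mean scope, arbitrary units.
#' @param sigma_tpc width of the performance dome, degrees C.
#' @return data.frame with columns `fish_id`, `temp_c`, `scope`.
#' @export
gen_lab_scope <- function(t_opt_lab = 24.8, n_per_temp = 10,
                          temps = c(12, 16.5, 21, 25.5, 30), seed = 1,
                          noise_cv = 0.15, scope_max = 6, sigma_tpc = 5) {
  if (any(temps < 12 | temps > 30)) stop("test temperatures must lie in [12, 30]")
  if (any(diff(temps) <= 0)) stop("test temperatures must be strictly increasing")
  if (n_per_temp <= 0) stop("n_per_temp must be positive")
  mean_scope <- scope_max * exp(-(temps - t_opt_lab)^2 / (2 * sigma_tpc^2))
  with_seed(seed, {
    temp_c <- rep(temps, each = n_per_temp)
    mu <- rep(mean_scope, each = n_per_temp)
    noise <- if (noise_cv > 0) exp(stats::rnorm(length(mu), 0, noise_cv)) else 1
    data.frame(
      fish_id = sprintf("fish_%02d_t%04.1f",
                        rep(seq_len(n_per_temp), times = length(temps)), temp_c),
      temp_c = temp_c,
      scope = mu * noise)
  })
}
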