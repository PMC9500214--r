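# Indirect calorimetry: Brockway power, steady-state breath averaging, net
# metabolic power and cost of transport.

#' Whole-body metabolic power from gas exchange (Brockway)
#'
#' `power = (16.58 kJ/L * vo2 + 4.51 kJ/L * vco2)` converted to watts. The
#' coefficients are the standard published energy equivalents; they can be
#' overridden (they are also carried in the run configuration).
#'
#' @param vo2 Oxygen consumption rate (L/min), >= 0.
#' @param vco2 Carbon dioxide production rate (L/min), >= 0.
#' @param coef_o2,coef_co2 Energy equivalents (kJ/L).
#' @return Metabolic power (W). Vectorized.
#' @examples
#' brockway_power(1, 0) # 16.58 kJ/min = 276.33 W
#' @export
brockway_power <- function(vo2, vco2, coef_o2 = 16.58, coef_co2 = 4.51) {
  if (any(vo2 < 0) || any(vco2 < 0)) stop("gas exchange rates must be >= 0")
  (coef_o2 * vo2 + coef_co2 * vco2) * 1000 / 60
}

#' Time-weighted steady-state average of a breath series
#'
#' Averages breaths whose timestamps fall in the final window, weighting each
#' breath by the time elapsed since the previous breath (robust to irregular
#' breath intervals; a plain mean would over-weight rapid breathing bouts).
#' The first in-window breath is weighted from the window start.
#'
#' @param breaths data.frame with columns `t` (s, strictly increasing),
#'   `vo2`, `vco2` (L/min).
#' @param window Averaging window length (s), taken from the end.
#' @param t_end End of the collection (s); default the last breath time.
#' @param min_breaths Minimum breaths required in the window.
#' @return Named numeric vector `c(vo2 = , vco2 = )`.
#' @export
steady_state_average <- function(breaths, window = 120, t_end = NULL,
                                 min_breaths = 5) {
  stopifnot(all(c("t", "vo2", "vco2") %in% names(breaths)))
  if (is.unsorted(breaths$t, strictly = TRUE)) {
    stop("breath timestamps must be strictly increasing")
  }
  if (is.null(t_end)) t_end <- max(breaths$t)
  t0 <- t_end - window
  sel <- which(breaths$t >= t0 & breaths$t <= t_end)
  if (length(sel) < min_breaths) {
    stop(sprintf("only %d breaths in the final %g s window (need >= %d)",
                 length(sel), window, min_breaths))
  }
  prev <- c(t0, breaths$t[sel[-length(sel)]])
  w <- breaths$t[sel] - prev
  c(vo2 = sum(w * breaths$vo2[sel]) / sum(w),
    vco2 = sum(w * breaths$vco2[sel]) / sum(w))
}

#' Net metabolic power
#'
#' Walking metabolic power minus the standing baseline, normalized by body
#' mass. Negative results are allowed but flagged with a warning (they signal
#' a baseline inconsistency, not a physiological outcome).
#'
#' @param walking_power Walking metabolic power (W).
#' @param standing_power Standing metabolic power (W).
#' @param mass Body mass (kg), > 0.
#' @return Net metabolic power (W/kg).
#' @export
net_metabolic_power <- function(walking_power, standing_power, mass) {
  if (!is.numeric(mass) || mass <= 0) stop("mass must be > 0")
  np <- (walking_power - standing_power) / mass
  if (any(np < 0)) warning("negative net metabolic power (walking < standing)")
  np
}

#' Cost of transport
#'
#' Net metabolic energy per unit distance traveled: net power per kilogram
#' divided by mean walking speed.
#'
#' @param net_power_per_kg Net metabolic power (W/kg).
#' @param mean_speed Mean walking speed (m/s), > 0.
#' @return Cost of transport (J/(kg m)). Vectorized.
#' @export
cost_of_transport <- function(net_power_per_kg, mean_speed) {
  if (any(mean_speed <= 0)) stop("mean_speed must be > 0")
  net_power_per_kg / mean_speed
}
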