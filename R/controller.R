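#' Self-paced treadmill controller state
#'
#' A dead-zone proportional controller: once per double support the average
#' anterior-posterior center-of-pressure position is compared against a dead
#' zone centered on the treadmill midline; outside it, belt speed changes by
#' `sign(cop) * |cop| * gain` (m/s), clipped to the speed bounds.
#'
#' @param belt_speed Initial belt speed (m/s); self-paced trials start at the
#'   participant's preferred overground speed.
#' @param dead_zone_halfwidth Half-width of the dead zone (m); default 0.10
#'   (the 20 cm dead zone).
#' @param gain Dimensionless proportional gain L; default 0.1.
#' @param speed_min,speed_max Belt speed bounds (m/s).
#' @return An object of class `fpclamp_controller`.
#' @export
controller_state <- function(belt_speed,
                             dead_zone_halfwidth = 0.10,
                             gain = 0.1,
                             speed_min = 0.2,
                             speed_max = 3.0) {
  stopifnot(dead_zone_halfwidth > 0, gain > 0,
            speed_min >= 0, speed_min <= speed_max)
  if (!is.finite(belt_speed) || belt_speed < speed_min || belt_speed > speed_max) {
    stop("belt_speed must lie within [speed_min, speed_max]")
  }
  structure(list(belt_speed = belt_speed,
                 dead_zone_halfwidth = dead_zone_halfwidth,
                 gain = gain,
                 speed_min = speed_min,
                 speed_max = speed_max,
                 last_update_time = NA_real_,
                 last_delta = 0,
                 bound_events = 0L),
            class = "fpclamp_controller")
}

#' Average center-of-pressure position over a double-support window
#'
#' Arithmetic mean of the anterior-posterior CoP samples whose timestamps fall
#' inside the window (anterior positive, treadmill-center origin).
#'
#' @param cop Numeric CoP series (m).
#' @param time Sample timestamps (s), same length as `cop`.
#' @param window Length-2 numeric `c(start, end)` of the double-support phase.
#' @return Mean CoP position (m).
#' @export
cop_double_support_average <- function(cop, time, window) {
  stopifnot(length(cop) == length(time), length(window) == 2, window[1] <= window[2])
  sel <- time >= window[1] & time <= window[2]
  if (!any(sel)) stop("empty double-support window: no CoP samples inside")
  mean(cop[sel])
}

#' Apply one controller speed update
#'
#' Implements the dead-zone proportional law: no change when the CoP average
#' lies inside the dead zone; otherwise the belt speed changes by R*D*L with
#' R the sign of the CoP average, D its distance from treadmill center (m) and
#' L the gain. The result is clipped to the controller's speed bounds. One
#' update is applied per double support.
#'
#' @param state A [controller_state()].
#' @param cop_avg Double-support average CoP position (m, anterior positive).
#' @param time Optional timestamp of the update (s), recorded for audit.
#' @return The updated controller state; `$last_delta` holds the applied
#'   speed change (0 inside the dead zone) and `$bound_events` counts updates
#'   clipped at a speed bound.
#' @export
speed_update <- function(state, cop_avg, time = NA_real_) {
  stopifnot(inherits(state, "fpclamp_controller"))
  if (!is.finite(cop_avg)) stop("cop_avg must be finite")
  delta <- if (abs(cop_avg) <= state$dead_zone_halfwidth) {
    0
  } else {
    sign(cop_avg) * abs(cop_avg) * state$gain
  }
  target <- state$belt_speed + delta
  clipped <- min(max(target, state$speed_min), state$speed_max)
  if (clipped != target) state$bound_events <- state$bound_events + 1L
  state$last_delta <- clipped - state$belt_speed
  state$belt_speed <- clipped
  state$last_update_time <- time
  state
}

#' Biofeedback state for F_P targeting
#'
#' @param target_fp Target peak propulsive force (N).
#' @param tolerance_frac On-target tolerance as a fraction of the target
#'   (default 0.05: "within 5%", inclusive).
#' @return An object of class `fpclamp_feedback`.
#' @export
feedback_state <- function(target_fp, tolerance_frac = 0.05) {
  stopifnot(target_fp > 0, tolerance_frac > 0)
  structure(list(target_fp = target_fp,
                 tolerance_frac = tolerance_frac,
                 displayed_fp = NA_real_,
                 on_target = FALSE,
                 streak = 0L),
            class = "fpclamp_feedback")
}

#' Update the biofeedback display with the last two step peaks
#'
#' The display shows the mean peak F_P of the previous two steps (one per
#' side); it is on target when the displayed value lies within the tolerance
#' band of the target, and a streak counter tracks consecutive on-target
#' updates. A missing side withholds the display and leaves the streak
#' unchanged.
#'
#' @param fb A [feedback_state()].
#' @param step_peaks Numeric length-2: the last left and right peak F_P (N).
#' @return Updated feedback state.
#' @export
feedback_update <- function(fb, step_peaks) {
  stopifnot(inherits(fb, "fpclamp_feedback"), length(step_peaks) == 2)
  if (anyNA(step_peaks)) {
    fb$displayed_fp <- NA_real_
    fb$on_target <- FALSE
    return(fb)
  }
  fb$displayed_fp <- mean(step_peaks)
  fb$on_target <- abs(fb$displayed_fp - fb$target_fp) <=
    fb$tolerance_frac * fb$target_fp
  fb$streak <- if (fb$on_target) fb$streak + 1L else 0L
  fb
}
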