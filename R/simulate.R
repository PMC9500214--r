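# Trial simulators: realize the calibrated trial-level structural model as raw
# force-plate / marker / belt / breath time series.

G <- 9.81

# one trial-level draw of the outcomes the raw signals must encode
draw_trial_targets <- function(profile, cal, clamp_type, intensity,
                               fp_target_n = NULL) {
  rs <- cal$residual_sds
  if (clamp_type == "speed") {
    v_intent <- profile$preferred_speed * (1 + intensity)
    fp_bw <- structural_fp_bw(cal, v_intent) + profile$fp_offset +
      stats::rnorm(1, 0, rs$fp / sqrt(2))
  } else {
    stopifnot(!is.null(fp_target_n), fp_target_n > 0)
    target_bw <- 100 * fp_target_n / (profile$mass * G)
    fp_bw <- target_bw * cal$clamp_offsets[["fp"]] *
      (1 + stats::rnorm(1, 0, rs$fp_track))
    # self-selected speed: invert the participant's own F_P-speed line, then
    # apply the F_P-clamp speed surcharge and trial-to-trial intent noise
    v_intent <- (fp_bw - cal$fp_intercept - profile$fp_offset) /
      cal$speed_fp_slope * cal$speed_clamp_extra *
      (1 + stats::rnorm(1, 0, rs$speed_intent))
    v_intent <- min(max(v_intent, 0.4), 2.8)
  }
  fb_bw <- structural_fb_bw(cal, v_intent) + profile$fb_offset +
    stats::rnorm(1, 0, rs$fb / sqrt(2))
  list(v_intent = v_intent,
       fp_bw = max(fp_bw, 5),
       fb_bw = max(fb_bw, 5),
       dur_eps = stats::rnorm(1, 0, rs$stride_dur / sqrt(2)))
}

simulate_trial_impl <- function(profile, config, clamp_type, intensity,
                                fp_target_n = NULL, controller = NULL,
                                trial_seed = NULL) {
  stopifnot(inherits(config, "fpclamp_config"))
  cal <- config$calibration
  ns_ <- cal$noise_scales
  rate <- config$analog_rate
  dur <- config$trial_duration
  if (!is.null(trial_seed)) set.seed(trial_seed)
  tt <- draw_trial_targets(profile, cal, clamp_type, intensity, fp_target_n)
  bw_n <- profile$mass * G

  nsamp <- floor(dur * rate) + 1L
  time <- (seq_len(nsamp) - 1) / rate
  grf_v <- list(L = numeric(nsamp), R = numeric(nsamp))
  grf_ap <- list(L = numeric(nsamp), R = numeric(nsamp))
  cop <- numeric(nsamp)

  selfpaced <- clamp_type == "fp"
  if (selfpaced) {
    if (is.null(controller)) controller <- controller_state(profile$preferred_speed)
    stopifnot(inherits(controller, "fpclamp_controller"))
  }
  b <- if (selfpaced) controller$belt_speed else tt$v_intent
  belt_t0 <- 0
  belt_speeds <- b          # piecewise-constant belt profile
  k_cop <- 1.5              # m of fore-aft drift per m/s of speed-intent mismatch

  steps <- list(side = character(0), hs = numeric(0), to = numeric(0),
                fp = numeric(0), fb = numeric(0), offset = numeric(0))
  trace <- list(time = numeric(0), cop_avg = numeric(0), delta = numeric(0),
                belt = numeric(0))
  fbstate <- if (selfpaced) feedback_state(fp_target_n) else NULL
  prev_peak <- NA_real_
  on_target_n <- 0L

  t_hs <- 0.4; side <- "L"; wander <- 0
  while (t_hs < dur - 0.3) {
    T_k <- (structural_stride_duration(cal, b) + profile$dur_offset + tt$dur_eps) *
      (1 + stats::rnorm(1, 0, ns_$timing_step))
    T_k <- max(T_k, 0.5)
    stance <- 0.6 * T_k
    fp_n <- tt$fp_bw / 100 * bw_n * (1 + stats::rnorm(1, 0, ns_$fp_step))
    fb_n <- max(tt$fb_bw / 100 * bw_n * (1 + stats::rnorm(1, 0, ns_$fb_step)), 1)
    wav <- generate_stance_waveforms(profile, b, fp_n, stance, rate,
                                     fb_peak = fb_n)
    i0 <- floor(t_hs * rate) + 1L
    idx <- i0:min(i0 + wav$n - 1L, nsamp)
    grf_v[[side]][idx] <- grf_v[[side]][idx] + wav$vertical[seq_along(idx)]
    grf_ap[[side]][idx] <- grf_ap[[side]][idx] + wav$ap[seq_along(idx)]

    # walker fore-aft position for this step
    if (selfpaced) {
      wander <- 0.85 * wander + stats::rnorm(1, 0, ns_$speed_wander)
      v_int_step <- tt$v_intent + wander
      offset <- k_cop * (v_int_step - b) + stats::rnorm(1, 0, ns_$cop)
    } else {
      offset <- stats::rnorm(1, 0, ns_$cop)
    }
    offset <- min(max(offset, -0.35), 0.35)
    seg_end <- min(floor((t_hs + T_k / 2) * rate), nsamp)
    seg <- i0:seg_end
    cop[seg] <- offset + 0.05 * sin(2 * pi * (time[seg] - t_hs) / T_k - 0.1 * pi)

    n <- length(steps$hs) + 1L
    steps$side[n] <- side; steps$hs[n] <- t_hs
    steps$to[n] <- t_hs + stance
    steps$fp[n] <- fp_n; steps$fb[n] <- fb_n; steps$offset[n] <- offset

    if (selfpaced) {
      ds_end <- t_hs + 0.1 * T_k
      di <- i0:min(floor(ds_end * rate) + 1L, nsamp)
      cop_avg <- cop_double_support_average(cop[di], time[di], c(t_hs, ds_end))
      controller <- speed_update(controller, cop_avg, ds_end)
      trace$time <- c(trace$time, ds_end)
      trace$cop_avg <- c(trace$cop_avg, cop_avg)
      trace$delta <- c(trace$delta, controller$last_delta)
      trace$belt <- c(trace$belt, controller$belt_speed)
      if (controller$belt_speed != b) {
        b <- controller$belt_speed
        belt_t0 <- c(belt_t0, ds_end)
        belt_speeds <- c(belt_speeds, b)
      }
      if (!is.na(prev_peak)) {
        fbstate <- feedback_update(fbstate, c(prev_peak, fp_n))
        on_target_n <- on_target_n + as.integer(fbstate$on_target)
      }
      prev_peak <- fp_n
    }
    t_hs <- t_hs + T_k / 2
    side <- if (side == "L") "R" else "L"
  }

  belt <- belt_speeds[findInterval(time, belt_t0)]
  # heel markers: on the belt during stance, linear swing to the next strike
  belt_disp <- cumsum(belt) / rate
  heel <- list(L = rep(NA_real_, nsamp), R = rep(NA_real_, nsamp))
  for (s in c("L", "R")) {
    isel <- which(steps$side == s)
    for (k in isel) {
      i0 <- floor(steps$hs[k] * rate) + 1L
      i1 <- min(floor(steps$to[k] * rate) + 1L, nsamp)
      h0 <- steps$offset[k] + 0.35 + stats::rnorm(1, 0, cal$noise_scales$heel)
      heel[[s]][i0:i1] <- h0 - (belt_disp[i0:i1] - belt_disp[i0])
    }
    known <- which(!is.na(heel[[s]]))
    heel[[s]] <- stats::approx(known, heel[[s]][known], xout = seq_len(nsamp),
                               rule = 2)$y
  }

  breaths <- generate_breath_series(profile, tt$v_intent, tt$fp_bw / 100,
                                    clamp_type, dur, cal,
                                    analysis_window = config$analysis_window)

  structure(list(
    participant_id = profile$id,
    clamp_type = clamp_type,
    intensity = intensity,
    time = time,
    grf_vertical_l = grf_v$L, grf_vertical_r = grf_v$R,
    grf_ap_l = grf_ap$L, grf_ap_r = grf_ap$R,
    cop_ap = cop,
    heel_ap_l = heel$L, heel_ap_r = heel$R,
    belt_speed = belt,
    breaths = breaths,
    meta = list(mass = profile$mass,
                preferred_speed = profile$preferred_speed,
                standing_power = profile$standing_power,
                fp_target_n = fp_target_n,
                v_intent = tt$v_intent,
                fp_bw_trial = tt$fp_bw,
                analog_rate = rate,
                analysis_window = config$analysis_window,
                trial_seed = trial_seed,
                bound_events = if (selfpaced) controller$bound_events else 0L,
                on_target_steps = if (selfpaced) on_target_n else NA_integer_,
                controller_trace = if (selfpaced) as.data.frame(trace) else NULL)
  ), class = "fpclamp_trial")
}

#' Simulate a fixed-speed (speed clamp) trial
#'
#' The belt runs at `preferred_speed * (1 + intensity)` for the whole trial;
#' per-step propulsive peaks are drawn around the speed-implied F_P from the
#' calibrated response line plus participant offset and trial/step noise.
#'
#' @param profile One-row participant profile from [make_cohort()].
#' @param intensity Relative condition intensity (e.g. -0.2 ... 0.2); must be
#'   one of the configured intensities.
#' @param config A [cohort_config()].
#' @param trial_seed Optional integer seed for this trial's random stream.
#' @return A `fpclamp_trial` object (raw time series plus breath table).
#' @export
simulate_fixed_speed_trial <- function(profile, intensity, config,
                                       trial_seed = NULL) {
  if (!any(abs(config$intensities - intensity) < 1e-9)) {
    stop("intensity is not one of the configured condition intensities")
  }
  simulate_trial_impl(profile, config, "speed", intensity,
                      trial_seed = trial_seed)
}

#' Simulate a self-paced (F_P clamp) trial
#'
#' Closed loop per step: the walker tracks the prescribed F_P target with
#' tracking noise, intends the speed its own F_P-speed relation implies (times
#' the F_P-clamp offset), drifts fore/aft on the treadmill proportionally to
#' the intent-belt mismatch, and the dead-zone controller updates belt speed
#' once per double support. The trial starts at the participant's preferred
#' speed. Hitting a controller speed bound is logged
#' (`meta$bound_events`) and the trial continues at the bound.
#'
#' @param profile One-row participant profile.
#' @param fp_target Target peak propulsive force (N), > 0.
#' @param config A [cohort_config()].
#' @param controller Optional [controller_state()]; defaults to one started at
#'   the participant's preferred speed.
#' @param intensity Condition-intensity label carried into the output.
#' @param trial_seed Optional integer seed.
#' @return A `fpclamp_trial` object; `meta$controller_trace` holds the
#'   per-double-support audit trace (time, CoP average, speed change, belt).
#' @export
simulate_selfpaced_trial <- function(profile, fp_target, config,
                                     controller = NULL, intensity = NA_real_,
                                     trial_seed = NULL) {
  stopifnot(fp_target > 0)
  simulate_trial_impl(profile, config, "fp", intensity,
                      fp_target_n = fp_target, controller = controller,
                      trial_seed = trial_seed)
}

#' @export
print.fpclamp_trial <- function(x, ...) {
  cat(sprintf("fpclamp trial: %s, %s clamp, intensity %+.0f%%, %.0f s at %g Hz, %d breaths\n",
              x$participant_id, x$clamp_type, 100 * x$intensity,
              max(x$time), x$meta$analog_rate, nrow(x$breaths)))
  invisible(x)
}

#' Generate a breath-by-breath gas-exchange series
#'
#' Sets steady-state V̇O₂/V̇CO₂ so that Brockway-derived gross power matches
#' the calibrated net-power response surface (net power rises with speed and
#' with F_P residuals off the pooled line, times the F_P-clamp surcharge)
#' plus participant and trial noise, on top of the standing baseline. A
#' first-order onset transient (30 s time constant) occupies the pre-window
#' minutes and is truncated to zero at the analysis-window boundary, so the
#' final-window average inverts exactly. Breath intervals are irregular
#' (2-5 s; exactly 3.5 s under zero noise).
#'
#' @param profile One-row participant profile.
#' @param mean_speed Trial-mean walking speed (m/s); 0 for standing.
#' @param mean_fp_frac Trial-mean peak F_P as fraction of body weight.
#' @param clamp_type `"speed"`, `"fp"`, or `"standing"`.
#' @param duration Collection duration (s), > 0.
#' @param calibration A [calibration_params()] object.
#' @param analysis_window Final averaging window (s).
#' @return data.frame with columns `t` (s), `vo2`, `vco2` (L/min).
#' @export
generate_breath_series <- function(profile, mean_speed, mean_fp_frac,
                                   clamp_type, duration,
                                   calibration = calibration_params(),
                                   analysis_window = 120) {
  stopifnot(duration > 0)
  cal <- calibration
  w_stand <- profile$standing_power * profile$mass
  if (clamp_type == "standing") {
    w_target <- w_stand
    w_start <- w_stand
  } else {
    np <- structural_net_power(cal, mean_speed, profile$preferred_speed,
                               fp_bw = 100 * mean_fp_frac) +
      profile$np_offset + stats::rnorm(1, 0, cal$residual_sds$net_power / sqrt(2))
    if (clamp_type == "fp") np <- np * cal$np_clamp_extra
    w_target <- (max(np, 0.2) + profile$standing_power) * profile$mass
    w_start <- w_stand
  }
  n_max <- ceiling(duration / 2) + 1
  iv <- if (cal$noise_scales$breath > 0) stats::runif(n_max, 2, 5) else rep(3.5, n_max)
  t <- cumsum(iv)
  t <- t[t <= duration]
  onset_end <- max(duration - analysis_window, 0)
  w_t <- w_target - (w_target - w_start) * exp(-t / 30)
  w_t[t >= onset_end] <- w_target
  vo2_clean <- 0.06 * w_t / (16.58 + 4.51 * cal$rer)
  e1 <- stats::rnorm(length(t), 0, cal$noise_scales$breath)
  e2 <- stats::rnorm(length(t), 0, cal$noise_scales$breath)
  data.frame(t = t,
             vo2 = vo2_clean * (1 + e1),
             vco2 = cal$rer * vo2_clean * (1 + e2))
}

#' Simulate a standing baseline collection
#'
#' @param profile One-row participant profile.
#' @param config A [cohort_config()].
#' @param trial_seed Optional integer seed.
#' @return data.frame of breath samples (`t`, `vo2`, `vco2`).
#' @export
simulate_standing_breaths <- function(profile, config, trial_seed = NULL) {
  if (!is.null(trial_seed)) set.seed(trial_seed)
  generate_breath_series(profile, 0, 0, "standing", config$trial_duration,
                         config$calibration, config$analysis_window)
}
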