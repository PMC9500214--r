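# Step-level processing: gait events from vertical GRF, propulsive/braking
# peaks from AP GRF, stride metrics from heel markers, trial summaries.

#' Detect gait events from a vertical ground-reaction-force series
#'
#' Heel strike is the instant the vertical GRF surpasses the threshold
#' (upward crossing); toe off is the subsequent drop below it. A debounce
#' merges crossings closer than `debounce` seconds (force-noise chatter) and
#' drops above-threshold bursts shorter than the debounce.
#'
#' @param vgrf Vertical GRF series (N), uniformly sampled.
#' @param time Sample timestamps (s) or `NULL` with `rate` given.
#' @param rate Sampling rate (Hz), used when `time` is `NULL`.
#' @param threshold Event threshold (N), default 20.
#' @param debounce Minimum event separation (s), default 0.05.
#' @return data.frame with columns `heel_strike`, `toe_off` (s), one row per
#'   stance, events paired in order. Zero rows (with a message) if the series
#'   never crosses the threshold.
#' @export
detect_gait_events <- function(vgrf, time = NULL, rate = NULL, threshold = 20,
                               debounce = 0.05) {
  stopifnot(threshold > 0)
  if (is.null(time)) {
    stopifnot(!is.null(rate), rate > 0)
    time <- (seq_along(vgrf) - 1) / rate
  }
  stopifnot(length(time) == length(vgrf))
  dt <- time[2] - time[1]
  above <- vgrf > threshold
  r <- rle(above)
  min_len <- max(1L, ceiling(debounce / dt))
  # merge sub-debounce dips inside a stance, then drop sub-debounce spikes
  if (length(r$lengths) > 2) {
    inner <- which(!r$values & r$lengths < min_len)
    inner <- inner[inner > 1 & inner < length(r$lengths)]
    if (length(inner)) {
      r$values[inner] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  spikes <- which(r$values & r$lengths < min_len)
  if (length(spikes)) {
    r$values[spikes] <- FALSE
    r <- rle(inverse.rle(r))
  }
  if (!any(r$values)) {
    message("vertical GRF never crosses the event threshold; no events")
    return(data.frame(heel_strike = numeric(0), toe_off = numeric(0)))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  hs <- time[starts[on]]
  to <- time[pmin(ends[on] + 1L, length(time))]
  keep <- to > hs
  data.frame(heel_strike = hs[keep], toe_off = to[keep])
}

#' Extract propulsive and braking peaks per stance
#'
#' For each stance, the peak propulsive force is the maximum anterior
#' (positive) AP force over the full stance; the peak braking force is the
#' magnitude of the most posterior (negative) AP force restricted to the
#' first half of stance, the half being split at the temporal midpoint
#' `(heel_strike + toe_off) / 2`.
#'
#' @param apgrf Anterior-posterior GRF series (N, anterior positive).
#' @param time Sample timestamps (s) or `NULL` with `rate`.
#' @param events data.frame from [detect_gait_events()].
#' @param side Side label stored in the records.
#' @param rate Sampling rate (Hz) when `time` is `NULL`.
#' @return data.frame of step records: `side`, `heel_strike`, `toe_off`,
#'   `stance_dur`, `peak_fp`, `peak_fp_time`, `peak_fb`, `peak_fb_time`,
#'   `flag_no_propulsion`. A stance without positive samples yields
#'   `peak_fp = 0` and is flagged.
#' @export
extract_step_peaks <- function(apgrf, time = NULL, events, side = "L",
                               rate = NULL) {
  if (is.null(time)) {
    stopifnot(!is.null(rate), rate > 0)
    time <- (seq_along(apgrf) - 1) / rate
  }
  n <- nrow(events)
  out <- data.frame(side = rep(side, n),
                    heel_strike = events$heel_strike,
                    toe_off = events$toe_off,
                    stance_dur = events$toe_off - events$heel_strike,
                    peak_fp = NA_real_, peak_fp_time = NA_real_,
                    peak_fb = NA_real_, peak_fb_time = NA_real_,
                    flag_no_propulsion = FALSE)
  # stance sample ranges via the uniform grid (cheap index arithmetic)
  dt <- if (length(time) > 1) time[2] - time[1] else 1
  lo <- pmax(ceiling((events$heel_strike - time[1]) / dt - 1e-9) + 1L, 1L)
  hi <- pmin(floor((events$toe_off - time[1]) / dt + 1e-9) + 1L, length(time))
  for (k in seq_len(n)) {
    sel <- lo[k]:hi[k]
    ap <- apgrf[sel]
    if (max(ap) > 0) {
      i <- which.max(ap)
      out$peak_fp[k] <- ap[i]
      out$peak_fp_time[k] <- time[sel[i]]
    } else {
      out$peak_fp[k] <- 0
      out$flag_no_propulsion[k] <- TRUE
    }
    mid <- (events$heel_strike[k] + events$toe_off[k]) / 2
    first <- sel[time[sel] <= mid]
    i <- which.min(apgrf[first])
    out$peak_fb[k] <- abs(min(apgrf[first]))
    out$peak_fb_time[k] <- time[first[i]]
  }
  out
}

#' Stride length and duration from heel markers
#'
#' Stride duration is the time between consecutive ipsilateral heel strikes.
#' Stride length is the heel-marker anterior-posterior displacement between
#' those instants plus the belt travel over the stride (lab-frame markers on
#' a treadmill would otherwise yield near-zero lengths).
#'
#' @param heel_ap Heel-marker AP position series (m, lab frame).
#' @param time Sample timestamps (s) or `NULL` with `rate`.
#' @param events Ipsilateral events data.frame ([detect_gait_events()]).
#' @param belt_speed Belt-speed series (m/s) on the same grid.
#' @param rate Sampling rate (Hz) when `time` is `NULL`.
#' @return data.frame per stride: `t_start`, `t_end`, `duration`, `length`,
#'   `low_confidence` (TRUE when only a single stride is available).
#' @export
stride_metrics <- function(heel_ap, time = NULL, events, belt_speed,
                           rate = NULL) {
  if (is.null(time)) {
    stopifnot(!is.null(rate), rate > 0)
    time <- (seq_along(heel_ap) - 1) / rate
  }
  hs <- events$heel_strike
  if (length(hs) < 2) stop("need at least two ipsilateral heel strikes")
  dt <- time[2] - time[1]
  disp <- c(0, cumsum((belt_speed[-1] + belt_speed[-length(belt_speed)]) / 2) * dt)
  idx <- findInterval(hs, time)
  dur <- diff(hs)
  len <- diff(heel_ap[idx]) + diff(disp[idx])
  data.frame(t_start = hs[-length(hs)], t_end = hs[-1],
             duration = dur, length = len,
             low_confidence = length(dur) == 1L)
}

#' Summarize one trial over its final analysis window
#'
#' Runs event detection, peak extraction, stride metrics and metabolic
#' processing on a raw trial and averages everything whose events fall inside
#' the final window. Forces are normalized to percent body weight using the
#' participant mass and g = 9.81 m/s^2.
#'
#' @param trial A `fpclamp_trial`.
#' @param standing_power_w Measured standing metabolic power (W). Default uses
#'   the profile's true standing power (exact baseline).
#' @param window Analysis window length (s), default the trial's configured
#'   final 120 s.
#' @param threshold Gait-event threshold (N).
#' @return One-row data.frame (trial summary): participant, clamp type,
#'   intensity, step/stride counts, `mean_speed` (m/s), `mean_fp`/`mean_fb`
#'   (%BW), `stride_length` (m), `stride_duration` (s), `speed_sd_within`
#'   (m/s), `net_power` (W/kg), `cot` (J/(kg m)), `low_confidence` (fewer
#'   than 10 steps in the window).
#' @export
summarize_trial <- function(trial, standing_power_w = NULL, window = NULL,
                            threshold = 20) {
  stopifnot(inherits(trial, "fpclamp_trial"))
  if (is.null(window)) window <- trial$meta$analysis_window
  t_end <- max(trial$time)
  if (t_end < window) stop("trial shorter than the analysis window")
  t0 <- t_end - window
  bw <- trial$meta$mass * G
  if (is.null(standing_power_w)) {
    standing_power_w <- trial$meta$standing_power * trial$meta$mass
  }

  steps_all <- list(); strides_all <- list()
  for (s in c("l", "r")) {
    ev <- detect_gait_events(trial[[paste0("grf_vertical_", s)]], trial$time,
                             threshold = threshold)
    if (nrow(ev) == 0) next
    steps_all[[s]] <- extract_step_peaks(trial[[paste0("grf_ap_", s)]],
                                         trial$time, ev, side = toupper(s))
    if (nrow(ev) >= 2) {
      strides_all[[s]] <- stride_metrics(trial[[paste0("heel_ap_", s)]],
                                         trial$time, ev, trial$belt_speed)
    }
  }
  steps <- do.call(rbind, steps_all)
  strides <- do.call(rbind, strides_all)
  in_win <- steps[steps$heel_strike >= t0, , drop = FALSE]
  st_win <- strides[strides$t_start >= t0, , drop = FALSE]

  sel <- trial$time >= t0
  mean_speed <- mean(trial$belt_speed[sel])
  speed_sd <- stats::sd(trial$belt_speed[sel])

  ss <- steady_state_average(trial$breaths, window = window, t_end = t_end)
  walking_w <- brockway_power(ss[["vo2"]], ss[["vco2"]])
  net_power <- net_metabolic_power(walking_w, standing_power_w, trial$meta$mass)
  cot <- cost_of_transport(net_power, mean_speed)

  data.frame(participant_id = trial$participant_id,
             clamp_type = trial$clamp_type,
             intensity = trial$intensity,
             n_steps = nrow(in_win),
             n_strides = if (is.null(st_win)) 0L else nrow(st_win),
             mean_speed = mean_speed,
             mean_fp = 100 * mean(in_win$peak_fp) / bw,
             mean_fb = 100 * mean(in_win$peak_fb) / bw,
             stride_length = if (is.null(st_win)) NA_real_ else mean(st_win$length),
             stride_duration = if (is.null(st_win)) NA_real_ else mean(st_win$duration),
             speed_sd_within = speed_sd,
             net_power = net_power,
             cot = cot,
             low_confidence = nrow(in_win) < 10,
             stringsAsFactors = FALSE)
}
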