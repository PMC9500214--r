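#' Configuration for a synthetic cohort run
#'
#' @param n_participants Number of virtual participants (>= 2).
#' @param intensities Ordered relative condition intensities; must include 0
#'   (the Norm condition at preferred speed / habitual F_P).
#' @param trial_duration Trial length in seconds.
#' @param analysis_window Final analysis window in seconds (strictly shorter
#'   than the trial).
#' @param packet_rate Data-packet rate of the emulated acquisition chain (Hz);
#'   recorded for provenance, the analog channels are what the pipeline reads.
#' @param analog_rate Analog force-sampling rate (Hz). Default 100 Hz keeps a
#'   full 20-participant run to a couple of minutes; the emulated instrument's
#'   native rate is 1000 Hz.
#' @param seed Integer root seed; every participant/trial stream is derived
#'   from it, so identical configs yield identical raw trials.
#' @param calibration A [calibration_params()] object.
#' @return An object of class `fpclamp_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          intensities = c(-0.2, -0.1, 0, 0.1, 0.2),
                          trial_duration = 300,
                          analysis_window = 120,
                          packet_rate = 20,
                          analog_rate = 100,
                          seed = 1,
                          calibration = calibration_params(intensities = intensities)) {
  if (!is.numeric(n_participants) || n_participants < 2) {
    stop("n_participants must be >= 2")
  }
  if (!0 %in% intensities) stop("intensities must include 0 (Norm)")
  if (trial_duration <= analysis_window) {
    stop("trial_duration must exceed analysis_window")
  }
  stopifnot(analog_rate > 0, packet_rate > 0, is.finite(seed))
  structure(list(n_participants = as.integer(n_participants),
                 intensities = intensities,
                 trial_duration = trial_duration,
                 analysis_window = analysis_window,
                 packet_rate = packet_rate,
                 analog_rate = analog_rate,
                 seed = as.integer(seed),
                 calibration = calibration),
            class = "fpclamp_config")
}

#' @export
print.fpclamp_config <- function(x, ...) {
  cat(sprintf("fpclamp cohort config: n=%d, intensities [%s], %gs trials (final %gs analyzed), %g Hz analog, seed %d\n",
              x$n_participants, paste(x$intensities, collapse = ", "),
              x$trial_duration, x$analysis_window, x$analog_rate, x$seed))
  invisible(x)
}

# deterministic child seed derivation: one root seed, fixed offsets per
# participant / trial stream; kept well below 2^31
child_seed <- function(root, participant = 0L, trial = 0L, extra = 0L) {
  (as.integer(root) %% 100000L) * 20011L + participant * 977L +
    trial * 89L + extra * 7L
}

#' Generate a virtual cohort
#'
#' Draws participant anthropometrics (age, height, mass) and behavioural
#' parameters from the calibrated population distributions. Habitual F_P is
#' placed on the pooled F_P-vs-speed line at the participant's preferred speed
#' plus an individual offset, so that pooled trial-level regressions recover
#' the calibrated slopes and R-squared values.
#'
#' @param config A [cohort_config()].
#' @return A data.frame of class `fpclamp_cohort`, one row per participant:
#'   identifier, anthropometrics, preferred speed, habitual F_P/F_B fractions,
#'   individual line offsets (in measurement units), stride-timing base,
#'   standing metabolic power (W/kg) and per-channel noise scales.
#' @examples
#' ch <- make_cohort(cohort_config(n_participants = 5, seed = 2))
#' mean(ch$preferred_speed)
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "fpclamp_config"))
  cal <- config$calibration
  n <- config$n_participants
  set.seed(child_seed(config$seed))
  rs <- cal$residual_sds
  # truncate preferred speed to a physiological band so the -20% condition
  # stays well above the controller's lower speed bound
  v <- pmin(pmax(rnorm(n, cal$pop_mean_speed, cal$pop_sd_speed), 0.9), 2.1)
  fp_off <- rnorm(n, 0, rs$fp / sqrt(2))   # participant offset, %BW
  fb_off <- rnorm(n, 0, rs$fb / sqrt(2))
  dur_off <- rnorm(n, 0, rs$stride_dur / sqrt(2))
  np_off <- rnorm(n, 0, rs$net_power / sqrt(2))
  cohort <- data.frame(
    id = sprintf("P%02d", seq_len(n)),
    age = rnorm(n, cal$pop_mean_age, cal$pop_sd_age),
    height = rnorm(n, cal$pop_mean_height, cal$pop_sd_height),
    mass = pmax(rnorm(n, cal$pop_mean_mass, cal$pop_sd_mass), 40),
    preferred_speed = v,
    habitual_fp_frac = (structural_fp_bw(cal, v) + fp_off) / 100,
    habitual_fb_frac = (structural_fb_bw(cal, v) + fb_off) / 100,
    fp_speed_slope = cal$speed_fp_slope,
    fp_offset = fp_off,
    fb_offset = fb_off,
    dur_offset = dur_off,
    np_offset = np_off,
    cadence_base = 1 / (structural_stride_duration(cal, v) + dur_off),
    standing_power = rnorm(n, cal$standing_power_mean, cal$standing_power_sd),
    noise_fp_step = cal$noise_scales$fp_step,
    noise_speed_wander = cal$noise_scales$speed_wander,
    noise_breath = cal$noise_scales$breath,
    stringsAsFactors = FALSE
  )
  stopifnot(all(cohort$mass > 0), all(cohort$preferred_speed > 0),
            all(cohort$habitual_fp_frac > 0), all(cohort$habitual_fp_frac < 1))
  class(cohort) <- c("fpclamp_cohort", "data.frame")
  attr(cohort, "config") <- config
  cohort
}

#' @export
print.fpclamp_cohort <- function(x, ...) {
  cat(sprintf("fpclamp cohort: %d participants; preferred speed %.2f +/- %.2f m/s; habitual F_P %.1f +/- %.1f %%BW\n",
              nrow(x), mean(x$preferred_speed), stats::sd(x$preferred_speed),
              100 * mean(x$habitual_fp_frac), 100 * stats::sd(x$habitual_fp_frac)))
  NextMethod()
}
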