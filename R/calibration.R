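#' Residual standard deviation implied by a target R-squared
#'
#' Inverts the variance decomposition \eqn{R^2 = \sigma^2_{signal} /
#' (\sigma^2_{signal} + \sigma^2_{resid})} to obtain the residual SD that a
#' linear response must carry for a pooled regression to explain a given
#' fraction of variance.
#'
#' @param signal_sd Standard deviation of the structural (noise-free) signal.
#' @param r2 Target squared Pearson correlation, in (0, 1].
#' @return Residual standard deviation (0 when `r2 == 1`).
#' @examples
#' residual_sd_for_r2(1, 0.5) # == 1: equal signal and residual variance
#' @export
residual_sd_for_r2 <- function(signal_sd, r2) {
  stopifnot(is.numeric(signal_sd), signal_sd >= 0)
  if (any(r2 <= 0 | r2 > 1)) stop("r2 must be in (0, 1]")
  signal_sd * sqrt((1 - r2) / r2)
}

#' Calibration parameters for the synthetic cohort
#'
#' Bundles the population anthropometrics, the pooled response lines relating
#' walking speed to peak propulsive force (F_P), peak braking force (F_B) and
#' stride timing, the clamp-type offsets, and the residual SDs that set how
#' much scatter each trial-level outcome carries around its structural value.
#'
#' Residual SDs for F_P and F_B are derived at call time by variance
#' decomposition (`residual_sd_for_r2()`) from the targeted speed-clamp
#' R-squared values, using the pooled speed variance implied by the population
#' parameters and condition intensities. The remaining constants (cost of
#' transport curvature and minimum, the net-power coupling to F_P residuals,
#' net-power and stride-duration residual SDs, the self-paced speed-intent
#' noise and the F_P-clamp metabolic surcharge) were solved once by a
#' trial-level least-squares calibration against the targeted group statistics
#' and are frozen here; the methods vignette documents the derivation.
#'
#' @param pop_mean_speed,pop_sd_speed Preferred overground walking speed,
#'   population mean and SD (m/s).
#' @param pop_mean_fp_frac,pop_sd_fp_frac Habitual peak F_P as a fraction of
#'   body weight, population mean and SD.
#' @param speed_fp_slope Pooled F_P-vs-speed slope, %BW per m/s.
#' @param fb_speed_slope Pooled F_B-vs-speed slope, %BW per m/s.
#' @param stride_dur_slope Stride-duration-vs-speed slope, s per m/s
#'   (negative: faster walking shortens the stride period).
#' @param stride_dur_mean Mean stride duration at the population mean speed (s).
#' @param clamp_offsets Named multiplicative offsets of the F_P clamp relative
#'   to the speed clamp: `speed`, `fp`, `net_power`, `cot`.
#' @param r2_targets Named targeted squared correlations used by the live
#'   variance decomposition (`fp_speed` and `fb_speed`, speed clamp).
#' @param intensities Condition intensities the decomposition assumes.
#' @param zero_noise Logical; if `TRUE` every population SD, residual SD and
#'   per-channel noise scale is set to zero (closure testing: the pipeline must
#'   then recover R-squared = 1 and the calibration slopes exactly).
#' @return An object of class `fpclamp_calibration` (a named list).
#' @examples
#' cal <- calibration_params()
#' cal$residual_sds$fp  # %BW scatter of trial-mean F_P about the pooled line
#' @export
calibration_params <- function(pop_mean_speed = 1.41,
                               pop_sd_speed = 0.09,
                               pop_mean_fp_frac = 0.220,
                               pop_sd_fp_frac = 0.023,
                               speed_fp_slope = 14.74,
                               fb_speed_slope = 16.99,
                               stride_dur_slope = -0.29,
                               stride_dur_mean = 1.09,
                               clamp_offsets = c(speed = 1.026, fp = 1.014,
                                                 net_power = 1.089, cot = 1.062),
                               r2_targets = c(fp_speed = 0.84, fb_speed = 0.63),
                               intensities = c(-0.2, -0.1, 0, 0.1, 0.2),
                               zero_noise = FALSE) {
  stopifnot(pop_mean_speed > 0, pop_mean_fp_frac > 0, pop_mean_fp_frac < 1)
  # pooled trial-mean speed variance across the speed-clamp design
  var_v <- (pop_mean_speed^2 + pop_sd_speed^2) * mean((1 + intensities)^2) -
    pop_mean_speed^2
  fp_mean_bw <- 100 * pop_mean_fp_frac
  resid <- list(
    # live variance decomposition against the targeted speed-clamp R^2
    fp = residual_sd_for_r2(speed_fp_slope * sqrt(var_v), r2_targets[["fp_speed"]]),
    fb = residual_sd_for_r2(fb_speed_slope * sqrt(var_v), r2_targets[["fb_speed"]]),
    # frozen from the design-time trial-level calibration solve
    stride_dur = 0.0684,   # s
    net_power = 0.697,     # W/kg
    speed_intent = 0.0774, # fractional, F_P-clamp self-selected speed
    fp_track = 0.02        # fractional, biofeedback target tracking
  )
  noise <- list(
    fp_step = 0.03,      # step-to-step F_P peak, fractional
    fb_step = 0.03,
    timing_step = 0.01,   # step interval, fractional
    # self-paced walker intent wander, AR(1) innovation in m/s. Additive (not
    # proportional to speed) so within-trial speed variability is independent
    # of the trial's speed and metabolic level by construction.
    speed_wander = 0.035,
    cop = 0.03,           # walker fore-aft positioning, m
    breath = 0.015,      # breath-by-breath gas volumes, fractional
    heel = 0.005         # heel-marker placement, m
  )
  cal <- list(
    pop_mean_speed = pop_mean_speed, pop_sd_speed = pop_sd_speed,
    pop_mean_fp_frac = pop_mean_fp_frac, pop_sd_fp_frac = pop_sd_fp_frac,
    pop_mean_mass = 75.6, pop_sd_mass = 13.7,
    pop_mean_height = 1.77, pop_sd_height = 0.11,
    pop_mean_age = 24.7, pop_sd_age = 5.2,
    speed_fp_slope = speed_fp_slope,
    fp_intercept = fp_mean_bw - speed_fp_slope * pop_mean_speed,
    fb_speed_slope = fb_speed_slope,
    fb_intercept = fp_mean_bw - fb_speed_slope * pop_mean_speed,
    stride_dur_slope = stride_dur_slope,
    stride_dur_intercept = stride_dur_mean - stride_dur_slope * pop_mean_speed,
    stride_len_slope = stride_dur_mean + stride_dur_slope * pop_mean_speed,
    clamp_offsets = clamp_offsets,
    r2_targets = r2_targets,
    intensities = intensities,
    # metabolic response surface: CoT(v) = cot_norm + curv * (v - kmin*V_i)^2
    cot_norm = 2.35,        # J/(kg m) at the CoT minimum
    econ_curvature = 3.323, # J s^2/(kg m^3)
    cot_min_frac = 0.92,    # CoT minimum sits at 0.92 x preferred speed
    np_fp_coupling = 0.2264,  # W/kg per %BW of F_P residual off the line
    np_clamp_extra = 1.0262,  # F_P-clamp surcharge beyond the faster-speed path
    standing_power_mean = 1.40, standing_power_sd = 0.15, # W/kg
    rer = 0.85,
    residual_sds = resid,
    noise_scales = noise,
    var_speed_pooled = var_v
  )
  # how far the F_P clamp moves speed beyond what the F_P offset alone implies
  # along the pooled line (printed +2.6% speed at +1.4% F_P)
  cal$speed_clamp_extra <- clamp_offsets[["speed"]] /
    (1 + (clamp_offsets[["fp"]] - 1) * fp_mean_bw /
       (speed_fp_slope * pop_mean_speed))
  if (zero_noise) {
    cal$pop_sd_speed <- 0
    cal$pop_sd_fp_frac <- 0
    cal$pop_sd_mass <- 0
    cal$pop_sd_height <- 0
    cal$pop_sd_age <- 0
    cal$standing_power_sd <- 0
    cal$residual_sds[] <- lapply(cal$residual_sds, function(x) 0)
    cal$noise_scales[] <- lapply(cal$noise_scales, function(x) 0)
  }
  class(cal) <- "fpclamp_calibration"
  cal
}

#' @export
print.fpclamp_calibration <- function(x, ...) {
  cat("fpclamp calibration\n")
  cat(sprintf("  preferred speed: %.2f +/- %.2f m/s; habitual F_P: %.1f +/- %.1f %%BW\n",
              x$pop_mean_speed, x$pop_sd_speed,
              100 * x$pop_mean_fp_frac, 100 * x$pop_sd_fp_frac))
  cat(sprintf("  pooled lines: F_P = %.2f + %.2f v; F_B = %.2f + %.2f v (%%BW, v in m/s)\n",
              x$fp_intercept, x$speed_fp_slope, x$fb_intercept, x$fb_speed_slope))
  cat(sprintf("  clamp offsets (F_P clamp / speed clamp): speed %.3f, F_P %.3f, net power %.3f, CoT %.3f\n",
              x$clamp_offsets[["speed"]], x$clamp_offsets[["fp"]],
              x$clamp_offsets[["net_power"]], x$clamp_offsets[["cot"]]))
  cat(sprintf("  residual SDs: F_P %.2f %%BW, F_B %.2f %%BW, stride dur %.3f s, net power %.2f W/kg\n",
              x$residual_sds$fp, x$residual_sds$fb,
              x$residual_sds$stride_dur, x$residual_sds$net_power))
  invisible(x)
}

# Structural (noise-free) trial-level responses ------------------------------

# stride duration (s) implied by trial-mean speed, before participant offsets
structural_stride_duration <- function(cal, speed) {
  cal$stride_dur_intercept + cal$stride_dur_slope * speed
}

# F_P (%BW) on the pooled line at a given speed
structural_fp_bw <- function(cal, speed) {
  cal$fp_intercept + cal$speed_fp_slope * speed
}

# F_B (%BW) on the pooled line
structural_fb_bw <- function(cal, speed) {
  cal$fb_intercept + cal$fb_speed_slope * speed
}

# cost of transport surface, J/(kg m); preferred_speed locates the minimum
structural_cot <- function(cal, speed, preferred_speed) {
  cal$cot_norm + cal$econ_curvature * (speed - cal$cot_min_frac * preferred_speed)^2
}

# net metabolic power surface, W/kg: v * CoT(v) plus coupling to how far the
# trial's F_P sits off the pooled line
structural_net_power <- function(cal, speed, preferred_speed, fp_bw = NULL) {
  np <- speed * structural_cot(cal, speed, preferred_speed)
  if (!is.null(fp_bw)) {
    np <- np + cal$np_fp_coupling * (fp_bw - structural_fp_bw(cal, speed))
  }
  np
}
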