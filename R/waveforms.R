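#' Generate single-stance ground-reaction-force waveforms
#'
#' Builds one stance phase of vertical and anterior-posterior (AP) GRF on a
#' uniform grid from a fixed low-order basis. The vertical channel is the
#' double-humped curve `A * (sin(pi x) + 0.25 sin(3 pi x))` (non-negative,
#' rising from and returning to zero). The AP channel is one negative
#' half-sine braking lobe centered in the first half of stance followed by one
#' positive half-sine propulsive lobe in the second half whose sampled maximum
#' equals `fp_peak` exactly. The braking lobe's width (and, for exactness, a
#' small amplitude rescale) is set so the discrete braking impulse balances
#' the propulsive impulse, as in steady-speed walking.
#'
#' @param profile One-row participant profile (needs `mass`); used to scale
#'   the vertical peak to body weight.
#' @param speed Walking speed (m/s); carried for interface symmetry, the
#'   waveform shape is speed-invariant by design.
#' @param fp_peak Peak propulsive force (N), > 0.
#' @param stance_dur Stance duration (s); must span at least 4 samples.
#' @param rate Sampling rate (Hz).
#' @param fb_peak Optional peak braking force magnitude (N). Default `NULL`
#'   mirrors `fp_peak` with equal lobe widths; when given, the braking lobe
#'   width absorbs the peak asymmetry so impulses still balance.
#' @param vertical_peak_bw Vertical GRF peak in units of body weight.
#' @param g Gravitational acceleration (m/s^2).
#' @return List with `vertical` and `ap` numeric vectors (`n` samples spanning
#'   `[0, stance_dur]` at `1/rate` spacing) plus `n` and `dt`.
#' @examples
#' p <- data.frame(mass = 75)
#' w <- generate_stance_waveforms(p, speed = 1.4, fp_peak = 160,
#'                                stance_dur = 0.66, rate = 100)
#' max(w$ap) # exactly 160
#' @export
generate_stance_waveforms <- function(profile, speed, fp_peak, stance_dur, rate,
                                      fb_peak = NULL, vertical_peak_bw = 1.12,
                                      g = 9.81) {
  stopifnot(fp_peak > 0, stance_dur > 0, rate > 0)
  n <- floor(stance_dur * rate) + 1L
  if (n < 4L) stop("stance_dur spans fewer than 4 samples at this rate")
  x <- seq(0, 1, length.out = n)
  # vertical: double-humped, strictly positive inside the stance
  vshape <- sin(pi * x) + 0.25 * sin(3 * pi * x)
  vertical <- vshape * (vertical_peak_bw * profile$mass * g / max(vshape))

  half_lobe <- function(x, center, width) {
    u <- (x - (center - width / 2)) / width
    out <- numeric(length(x))
    inside <- u > 0 & u < 1
    out[inside] <- sin(pi * u[inside])
    out
  }
  w_p <- 0.30
  prop <- half_lobe(x, center = 0.75, width = w_p)
  prop <- prop * (fp_peak / max(prop))           # sampled max == fp_peak
  if (is.null(fb_peak)) fb_peak <- fp_peak
  w_b <- min(max(w_p * fp_peak / fb_peak, 0.08), 0.44)
  brake <- half_lobe(x, center = 0.26, width = w_b)
  brake <- brake * (fb_peak / max(brake))
  # exact discrete impulse balance (braking amplitude rescale, ~1%)
  brake <- brake * (sum(prop) / sum(brake))
  list(vertical = vertical, ap = prop - brake, n = n, dt = 1 / rate)
}
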