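# Gait event detection, peak extraction, stride metrics, trial summaries.

test_that("a single synthetic stance yields exactly one event pair", {
  w <- generate_stance_waveforms(data.frame(mass = 75), 1.4, 160,
                                 stance_dur = 0.66, rate = 100)
  pad <- numeric(50)
  v <- c(pad, w$vertical, pad)
  ev <- detect_gait_events(v, rate = 100)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$heel_strike - 0.5), 0.03)
  expect_lt(abs(ev$toe_off - (0.5 + 0.66)), 0.03)
  expect_message(ev0 <- detect_gait_events(numeric(200), rate = 100), "no events")
  expect_equal(nrow(ev0), 0)
})

test_that("debounce keeps the event count stable under force noise", {
  set.seed(21)
  w <- generate_stance_waveforms(data.frame(mass = 75), 1.4, 160,
                                 stance_dur = 0.66, rate = 100)
  clean <- c(numeric(40), w$vertical, numeric(40), w$vertical, numeric(40))
  n_clean <- nrow(detect_gait_events(clean, rate = 100))
  for (i in 1:10) {
    noisy <- pmax(clean + stats::rnorm(length(clean), 0, 2), 0)
    expect_equal(nrow(detect_gait_events(noisy, rate = 100)), n_clean)
  }
  # an explicit sub-debounce dip mid-stance must not split the stance
  dipped <- clean
  dip_at <- 40 + 33
  dipped[dip_at:(dip_at + 2)] <- 5
  expect_equal(nrow(detect_gait_events(dipped, rate = 100)), n_clean)
})

test_that("step peaks equal a brute-force scan and respect the stance-half rule", {
  set.seed(22)
  rate <- 100
  for (i in 1:15) {
    fp <- stats::runif(1, 100, 250)
    fb <- fp * stats::runif(1, 0.8, 1.2)
    dur <- stats::runif(1, 0.55, 0.75)
    w <- generate_stance_waveforms(data.frame(mass = 75), 1.4, fp, dur, rate,
                                   fb_peak = fb)
    v <- c(numeric(30), w$vertical, numeric(30))
    ap <- c(numeric(30), w$ap, numeric(30))
    time <- (seq_along(v) - 1) / rate
    ev <- detect_gait_events(v, time)
    st <- extract_step_peaks(ap, time, ev)
    # independent exhaustive-scan oracle
    sel <- which(time >= ev$heel_strike & time <= ev$toe_off)
    expect_equal(st$peak_fp, max(ap[sel]))
    mid <- (ev$heel_strike + ev$toe_off) / 2
    first <- sel[time[sel] <= mid]
    expect_equal(st$peak_fb, abs(min(ap[first])))
    expect_lt(st$peak_fb_time, mid)
  }
})

test_that("braking restricted to first half differs from the global minimum", {
  rate <- 100
  time <- (0:99) / rate
  ap <- numeric(100)
  ap[10:90] <- 10                       # stance marker forces via vertical below
  v <- numeric(100); v[10:90] <- 800
  ap[20:30] <- -40                      # early (true) braking
  ap[70:80] <- -90                      # late negative excursion: must be ignored
  ev <- detect_gait_events(v, time)
  st <- extract_step_peaks(ap, time, ev)
  expect_equal(st$peak_fb, 40)
  expect_false(isTRUE(all.equal(st$peak_fb, abs(min(ap)))))
})

test_that("a stance without propulsion yields zero peak and a flag", {
  rate <- 100
  v <- numeric(100); v[10:60] <- 500
  ap <- numeric(100); ap[10:60] <- -30
  st <- extract_step_peaks(ap, rate = rate, events = detect_gait_events(v, rate = rate))
  expect_equal(st$peak_fp, 0)
  expect_true(st$flag_no_propulsion)
})

test_that("stride metrics obey the kinematic identity with belt correction", {
  rate <- 100
  v <- 1.3; T_str <- 1.1
  time <- seq(0, 10, by = 1 / rate)
  hs <- seq(0.5, 9.5, by = T_str)
  events <- data.frame(heel_strike = hs, toe_off = hs + 0.6 * T_str)
  heel <- rep(0.3, length(time))        # walker perfectly stationary in lab frame
  belt <- rep(v, length(time))
  sm <- stride_metrics(heel, time, events, belt)
  expect_equal(sm$duration, rep(T_str, nrow(sm)))
  expect_equal(sm$length, rep(v * T_str, nrow(sm)), tolerance = 1e-10)
  # doubling belt speed at fixed cadence doubles stride length
  sm2 <- stride_metrics(heel, time, events, 2 * belt)
  expect_equal(sm2$length, 2 * sm$length, tolerance = 1e-10)
  expect_error(stride_metrics(heel, time, events[1, ], belt), "two ipsilateral")
})

test_that("simulated-trial stride metrics are self-consistent", {
  run <- tiny_run()
  s <- run$summaries
  expect_true(all(abs(s$stride_length - s$mean_speed * s$stride_duration) /
                    s$stride_length < 0.05))
})

test_that("zero-noise Norm trial summaries round-trip the profile exactly", {
  cc <- tiny_config(n = 2, seed = 33, zero_noise = TRUE)
  ch <- make_cohort(cc)
  prof <- ch[1, ]
  tr <- simulate_fixed_speed_trial(prof, 0, cc, trial_seed = 4)
  expect_equal(mean(tr$belt_speed), prof$preferred_speed)
  s <- summarize_trial(tr)
  expect_equal(s$mean_speed, prof$preferred_speed)
  expect_equal(s$mean_fp, 100 * prof$habitual_fp_frac, tolerance = 1e-9)
})

test_that("only steps inside the final window contribute to the summary", {
  cc <- tiny_config(n = 2, seed = 34)
  ch <- make_cohort(cc)
  tr <- simulate_fixed_speed_trial(ch[1, ], 0, cc, trial_seed = 5)
  s <- summarize_trial(tr, window = 60)
  # manual recomputation from raw arrays (window discipline oracle)
  t0 <- max(tr$time) - 60
  peaks <- c()
  for (side in c("l", "r")) {
    ev <- detect_gait_events(tr[[paste0("grf_vertical_", side)]], tr$time)
    st <- extract_step_peaks(tr[[paste0("grf_ap_", side)]], tr$time, ev)
    peaks <- c(peaks, st$peak_fp[st$heel_strike >= t0])
  }
  expect_equal(s$n_steps, length(peaks))
  expect_equal(s$mean_fp, 100 * mean(peaks) / (tr$meta$mass * 9.81))
})
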