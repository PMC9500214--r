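# Trial simulators: determinism, clamp semantics, zero-noise closure.

test_that("identical config and seed reproduce identical raw trials", {
  cc <- tiny_config(n = 2, seed = 61)
  ch <- make_cohort(cc)
  t1 <- simulate_fixed_speed_trial(ch[1, ], 0.1, cc, trial_seed = 3)
  t2 <- simulate_fixed_speed_trial(ch[1, ], 0.1, cc, trial_seed = 3)
  expect_identical(t1[setdiff(names(t1), "meta")],
                   t2[setdiff(names(t2), "meta")])
  expect_identical(t1$breaths, t2$breaths)
})

test_that("speed clamp fixes the belt and scales F_P monotonically", {
  cc <- tiny_config(n = 2, seed = 62, zero_noise = TRUE)
  ch <- make_cohort(cc)
  prof <- ch[1, ]
  tr0 <- simulate_fixed_speed_trial(prof, 0, cc, trial_seed = 1)
  expect_true(all(tr0$belt_speed == prof$preferred_speed))
  tr20 <- simulate_fixed_speed_trial(prof, 0.2, cc, trial_seed = 2)
  s0 <- summarize_trial(tr0); s20 <- summarize_trial(tr20)
  # zero noise: every step peak identical, larger at higher intensity
  ev <- detect_gait_events(tr20$grf_vertical_l, tr20$time)
  pk <- extract_step_peaks(tr20$grf_ap_l, tr20$time, ev)
  inner <- pk$peak_fp[pk$toe_off < max(tr20$time) - 1]
  expect_lt(diff(range(inner)), 1e-9)
  expect_gt(s20$mean_fp, s0$mean_fp)
  expect_error(simulate_fixed_speed_trial(prof, 0.15, cc), "intensities")
})

test_that("zero-noise closure: pipeline recovers the calibration line exactly", {
  cc <- cohort_config(n_participants = 4, trial_duration = 120,
                      analysis_window = 60, seed = 63,
                      calibration = calibration_params(zero_noise = TRUE))
  ch <- make_cohort(cc)
  rows <- list()
  for (p in 1:4) for (j in cc$intensities) {
    tr <- simulate_fixed_speed_trial(ch[p, ], j, cc,
                                     trial_seed = fpclamp:::child_seed(63, p, round(10 * j)))
    rows[[length(rows) + 1]] <- summarize_trial(tr)
  }
  s <- do.call(rbind, rows)
  fit <- stats::lm(mean_fp ~ mean_speed, data = s)
  cal <- cc$calibration
  expect_equal(unname(stats::coef(fit)[2]), cal$speed_fp_slope, tolerance = 1e-6)
  expect_equal(unname(stats::coef(fit)[1]), cal$fp_intercept, tolerance = 1e-6)
  # suppress summary.lm's "essentially perfect fit" note: the perfect fit IS
  # the zero-noise closure property under test
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-9)
})

test_that("generated forces stay physiologically plausible", {
  run <- tiny_run()
  cc <- tiny_config()
  ch <- run$cohort
  for (p in seq_len(nrow(ch))) {
    tr <- simulate_fixed_speed_trial(ch[p, ], 0.2, cc,
                                     trial_seed = 900 + p)
    bw <- ch$mass[p] * 9.81
    for (side in c("l", "r")) {
      ev <- detect_gait_events(tr[[paste0("grf_vertical_", side)]], tr$time)
      ev <- ev[ev$toe_off < max(tr$time) - 1, ]
      pk <- extract_step_peaks(tr[[paste0("grf_ap_", side)]], tr$time, ev)
      vmax <- vapply(seq_len(nrow(ev)), function(k) {
        sel <- tr$time >= ev$heel_strike[k] & tr$time <= ev$toe_off[k]
        max(tr[[paste0("grf_vertical_", side)]][sel])
      }, numeric(1))
      expect_true(all(vmax / bw > 0.8 & vmax / bw < 1.5))
      expect_true(all(pk$peak_fp / bw > 0.05 & pk$peak_fp / bw < 0.45))
    }
  }
})

test_that("self-paced speed stabilizes after the initial transient", {
  run <- tiny_run()
  cc <- tiny_config()
  ch <- run$cohort
  rel <- matrix(NA_real_, nrow(ch), 2)
  for (p in seq_len(nrow(ch))) {
    tgt <- ch$habitual_fp_frac[p] * ch$mass[p] * 9.81
    tr <- simulate_selfpaced_trial(ch[p, ], tgt, cc, intensity = 0,
                                   trial_seed = 950 + p)
    v <- tr$belt_speed / tr$meta$v_intent
    early <- v[tr$time <= 30]; late <- v[tr$time >= 60]
    rel[p, ] <- c(stats::sd(early), stats::sd(late))
  }
  # group-averaged wander after stabilization is smaller than the transient
  expect_lt(mean(rel[, 2]), mean(rel[, 1]))
})

test_that("breath series respects clamp semantics", {
  cal <- calibration_params(zero_noise = TRUE)
  prof <- data.frame(id = "Z", mass = 80, preferred_speed = 1.4,
                     standing_power = 1.5, np_offset = 0)
  br <- generate_breath_series(prof, 1.4, 0.22, "speed", 300, cal)
  expect_true(all(diff(br$t) > 0))
  expect_true(all(br$vo2 >= 0 & br$vco2 >= 0))
  # vco2/vo2 ratio equals the configured RER
  expect_equal(br$vco2 / br$vo2, rep(cal$rer, nrow(br)))
})
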