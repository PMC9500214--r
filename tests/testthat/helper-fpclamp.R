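# Shared fixtures: small configs and memoized mini runs so expensive
# simulations are built once per test session.

tiny_config <- function(n = 3, seed = 101, zero_noise = FALSE) {
  cal <- calibration_params(zero_noise = zero_noise)
  cohort_config(n_participants = n, trial_duration = 120,
                analysis_window = 60, seed = seed, calibration = cal)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

tiny_run <- function() {
  memo("tiny_run", {
    rc <- run_config(n_participants = 3, trial_duration = 120,
                     analysis_window = 60, seed = 101)
    run_cohort(rc)
  })
}

# a 2x5 repeated-measures table with known injected structure
make_rm_table <- function(n_subj = 8, clamp_effect = 0, intensity_slope = 0,
                          noise_sd = 0, seed = 5) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("S%02d", seq_len(n_subj)),
                   clamp_type = c("speed", "fp"),
                   intensity = c(-0.2, -0.1, 0, 0.1, 0.2),
                   stringsAsFactors = FALSE)
  subj_off <- stats::rnorm(n_subj, 0, 1)
  names(subj_off) <- sprintf("S%02d", seq_len(n_subj))
  g$y <- 10 + subj_off[g$participant_id] +
    clamp_effect * (g$clamp_type == "fp") +
    intensity_slope * g$intensity +
    stats::rnorm(nrow(g), 0, noise_sd)
  g
}
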