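# Orchestration: full clamp experiment on a synthetic cohort, target
# validation, and the acceptance metric set.

#' Full run configuration
#'
#' Bundles the cohort configuration with controller defaults, metabolic
#' coefficients and analysis options into one serializable object
#' (see [save_run_config()]).
#'
#' @param n_participants,intensities,trial_duration,analysis_window,packet_rate,analog_rate,seed
#'   Passed to [cohort_config()].
#' @param zero_noise Build the calibration with every noise source zeroed
#'   (closure testing).
#' @param dead_zone_halfwidth,gain,speed_min,speed_max Controller defaults.
#' @param coef_o2,coef_co2 Brockway energy equivalents (kJ/L).
#' @param rer Respiratory exchange ratio used by the breath generator.
#' @param window Analysis window (s), shared by gait and metabolic averaging.
#' @param alpha ANOVA significance level.
#' @return An object of class `fpclamp_runconfig`.
#' @export
run_config <- function(n_participants = 20,
                       intensities = c(-0.2, -0.1, 0, 0.1, 0.2),
                       trial_duration = 300, analysis_window = 120,
                       packet_rate = 20, analog_rate = 100, seed = 1,
                       zero_noise = FALSE,
                       dead_zone_halfwidth = 0.10, gain = 0.1,
                       speed_min = 0.2, speed_max = 3.0,
                       coef_o2 = 16.58, coef_co2 = 4.51, rer = 0.85,
                       window = analysis_window, alpha = 0.05) {
  cal <- calibration_params(intensities = intensities, zero_noise = zero_noise)
  cal$rer <- rer
  cohort <- cohort_config(n_participants = n_participants,
                          intensities = intensities,
                          trial_duration = trial_duration,
                          analysis_window = analysis_window,
                          packet_rate = packet_rate,
                          analog_rate = analog_rate,
                          seed = seed, calibration = cal)
  structure(list(cohort = cohort,
                 zero_noise = zero_noise,
                 controller = list(dead_zone_halfwidth = dead_zone_halfwidth,
                                   gain = gain, speed_min = speed_min,
                                   speed_max = speed_max),
                 metabolic = list(coef_o2 = coef_o2, coef_co2 = coef_co2,
                                  rer = rer),
                 analysis = list(window = window, alpha = alpha)),
            class = "fpclamp_runconfig")
}

as_runconfig <- function(config) {
  if (inherits(config, "fpclamp_runconfig")) return(config)
  if (inherits(config, "fpclamp_config")) {
    rc <- run_config()
    rc$cohort <- config
    rc$analysis$window <- config$analysis_window
    return(rc)
  }
  stop("config must be a run_config() or cohort_config() object")
}

#' Simulate and process the complete clamp experiment
#'
#' For each participant: a standing baseline collection; five fixed-speed
#' (speed clamp) trials at the configured intensities; extraction of each
#' trial's mean peak F_P to use as the biofeedback target; five self-paced
#' (F_P clamp) trials at those targets. Every trial is reduced to a
#' final-window summary through the gait and metabolic processing chain.
#'
#' @param config A [run_config()] (or bare [cohort_config()]).
#' @param out_dir Optional directory: raw trials are streamed to disk as they
#'   are simulated (see `write_raw`).
#' @param write_raw Write raw trial tables under `out_dir/trials` (requires
#'   `out_dir`).
#' @param quiet Suppress progress messages.
#' @return List of class `fpclamp_run`: `summaries` (one row per trial),
#'   `cohort`, `standing_w` (measured standing power, W), `fp_targets` (N),
#'   `failures` (character log of per-trial failures; the run continues past
#'   them), `config`.
#' @export
run_cohort <- function(config, out_dir = NULL, write_raw = FALSE,
                       quiet = TRUE) {
  rc <- as_runconfig(config)
  cc <- rc$cohort
  cohort <- make_cohort(cc)
  g <- 9.81
  trial_dir <- if (write_raw && !is.null(out_dir)) file.path(out_dir, "trials")
  failures <- character(0)
  rows <- list()
  standing_w <- numeric(nrow(cohort))
  fp_targets <- list()

  for (p in seq_len(nrow(cohort))) {
    prof <- cohort[p, ]
    breaths <- simulate_standing_breaths(prof, cc,
                                         trial_seed = child_seed(cc$seed, p, 0L))
    ss <- steady_state_average(breaths, window = rc$analysis$window,
                               t_end = cc$trial_duration)
    standing_w[p] <- brockway_power(ss[["vo2"]], ss[["vco2"]],
                                    rc$metabolic$coef_o2, rc$metabolic$coef_co2)
    if (!is.null(trial_dir)) {
      if (!dir.exists(trial_dir)) dir.create(trial_dir, recursive = TRUE)
      data.table::fwrite(breaths,
                         file.path(trial_dir,
                                   paste0(prof$id, "_standing_breaths.tsv")),
                         sep = "\t")
    }
    targets_p <- numeric(length(cc$intensities))
    for (phase in c("speed", "fp")) {
      for (k in seq_along(cc$intensities)) {
        j <- cc$intensities[k]
        idx <- k + if (phase == "fp") length(cc$intensities) else 0L
        res <- tryCatch({
          trial <- if (phase == "speed") {
            simulate_fixed_speed_trial(prof, j, cc,
                                       trial_seed = child_seed(cc$seed, p, idx))
          } else {
            ctrl <- controller_state(prof$preferred_speed,
                                     rc$controller$dead_zone_halfwidth,
                                     rc$controller$gain,
                                     rc$controller$speed_min,
                                     rc$controller$speed_max)
            simulate_selfpaced_trial(prof, targets_p[k], cc,
                                     controller = ctrl, intensity = j,
                                     trial_seed = child_seed(cc$seed, p, idx))
          }
          if (!is.null(trial_dir)) write_trial(trial, trial_dir)
          summarize_trial(trial, standing_power_w = standing_w[p],
                          window = rc$analysis$window)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, sprintf("%s %s %+d%%: %s", prof$id, phase,
                                          round(100 * j), conditionMessage(res)))
          next
        }
        if (phase == "speed") {
          targets_p[k] <- res$mean_fp / 100 * prof$mass * g
        }
        rows[[length(rows) + 1]] <- res
      }
    }
    fp_targets[[prof$id]] <- targets_p
    if (!quiet) message(sprintf("participant %s done (%d/%d)", prof$id, p,
                                nrow(cohort)))
  }
  structure(list(summaries = do.call(rbind, rows), cohort = cohort,
                 standing_w = standing_w, fp_targets = fp_targets,
                 failures = failures, config = rc),
            class = "fpclamp_run")
}

#' Correlation and ANOVA analysis of a summary table
#'
#' @param summaries Trial summary table from [run_cohort()].
#' @param alpha ANOVA significance level.
#' @return List with `associations` (stacked [association()] tables for the
#'   speed/F_P/F_B/stride/metabolic pairs), `anovas` (one [rm_anova()] per
#'   outcome), and `speed_variability` ([speed_variability_check()]).
#' @export
analyze_summaries <- function(summaries, alpha = 0.05) {
  pairs <- list(c("mean_speed", "mean_fp"), c("mean_speed", "mean_fb"),
                c("mean_speed", "stride_length"),
                c("mean_speed", "stride_duration"),
                c("mean_speed", "net_power"), c("mean_speed", "cot"),
                c("mean_fp", "net_power"), c("mean_fp", "cot"))
  assoc <- do.call(rbind, lapply(pairs, function(pr) {
    association(summaries, pr[1], pr[2])
  }))
  dvs <- c("mean_speed", "mean_fp", "net_power", "cot")
  anovas <- lapply(dvs, function(dv) rm_anova(summaries, dv, alpha = alpha))
  names(anovas) <- dvs
  list(associations = assoc, anovas = anovas,
       speed_variability = speed_variability_check(summaries))
}

#' Run the full experiment and write all outputs
#'
#' Executes [run_cohort()] and [analyze_summaries()] and writes the summary
#' table, association and ANOVA reports, the speed-variability check, a
#' human-readable run report and the resolved configuration (YAML, including
#' the seed) into `out_dir` for exact reproduction.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param write_raw Also write every raw trial table (10 per participant,
#'   plus standing breath tables).
#' @param quiet Suppress progress messages.
#' @return The `fpclamp_run` object, invisibly, with `$analysis` attached.
#'   Per-trial failures are logged in the report and reflected in
#'   `$failures`; the run itself continues.
#' @export
run_full_experiment <- function(config = run_config(), out_dir,
                                write_raw = TRUE, quiet = TRUE) {
  rc <- as_runconfig(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  run <- run_cohort(rc, out_dir = out_dir, write_raw = write_raw,
                    quiet = quiet)
  an <- analyze_summaries(run$summaries, alpha = rc$analysis$alpha)
  run$analysis <- an

  data.table::fwrite(run$summaries, file.path(out_dir, "summaries.tsv"),
                     sep = "\t")
  data.table::fwrite(an$associations, file.path(out_dir, "associations.tsv"),
                     sep = "\t")
  eff <- do.call(rbind, lapply(an$anovas, function(a) {
    cbind(dv = a$dv, a$effects)
  }))
  data.table::fwrite(eff, file.path(out_dir, "anova_effects.tsv"), sep = "\t")
  post <- do.call(rbind, lapply(an$anovas, function(a) {
    if (nrow(a$posthoc)) cbind(dv = a$dv, a$posthoc) else NULL
  }))
  if (!is.null(post)) {
    data.table::fwrite(post, file.path(out_dir, "anova_posthoc.tsv"), sep = "\t")
  }
  data.table::fwrite(an$speed_variability,
                     file.path(out_dir, "speed_variability.tsv"), sep = "\t")
  save_run_config(rc, file.path(out_dir, "config.yaml"))

  rpt <- file.path(out_dir, "run_report.txt")
  con <- file(rpt, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("fpclamp run: %d participants x %d intensities x 2 clamps, seed %d",
            nrow(run$cohort), length(rc$cohort$intensities), rc$cohort$seed),
    sprintf("trials summarized: %d; failures: %d", nrow(run$summaries),
            length(run$failures)),
    run$failures,
    "",
    "Associations (per clamp + cross-clamp average):",
    utils::capture.output(print(as.data.frame(an$associations), digits = 3)),
    "",
    "Repeated-measures ANOVAs:",
    unlist(lapply(an$anovas, function(a) utils::capture.output(print(a))))
  ), con)
  invisible(run)
}

# The group statistics the synthetic cohort is calibrated to reproduce.
# `validate_targets()` compares a run against this table; R^2 tolerances
# 0.08, percent offsets 2 percentage points.
#' Calibration target table
#' @return data.frame: `metric`, `target`, `tol`.
#' @export
fpclamp_targets <- function() {
  data.frame(
    metric = c("r2_speed_fp_speedclamp", "r2_speed_fp_avg", "r2_speed_fb_avg",
               "r2_speed_stride_length_avg", "r2_fp_net_power_avg",
               "r2_speed_net_power_avg", "r2_fp_cot_avg", "np_offset_pct"),
    target = c(0.84, 0.80, 0.67, 0.72, 0.59, 0.54, 0.17, 8.9),
    tol = c(0.08, 0.08, 0.08, 0.08, 0.08, 0.08, 0.08, 2),
    stringsAsFactors = FALSE
  )
}

#' Recover the calibrated group statistics from a summary table
#'
#' @param summaries Trial summary table.
#' @return Named list of metrics: per-clamp and cross-clamp-average
#'   R-squared values for the speed/F_P/F_B/stride/metabolic associations,
#'   and the F_P-clamp percent offsets of speed, F_P, net power and CoT.
#' @export
metrics_from_summaries <- function(summaries) {
  r2_of <- function(x, y) {
    a <- association(summaries, x, y)
    list(speed = a$r2[a$group == "speed"], fp = a$r2[a$group == "fp"],
         avg = a$r2[a$group == "average"])
  }
  fp <- r2_of("mean_speed", "mean_fp")
  fb <- r2_of("mean_speed", "mean_fb")
  sl <- r2_of("mean_speed", "stride_length")
  sd_ <- r2_of("mean_speed", "stride_duration")
  npv <- r2_of("mean_speed", "net_power")
  npf <- r2_of("mean_fp", "net_power")
  cotv <- r2_of("mean_speed", "cot")
  cotf <- r2_of("mean_fp", "cot")
  gm <- function(v, clamp) mean(summaries[[v]][summaries$clamp_type == clamp])
  off <- function(v) 100 * (gm(v, "fp") / gm(v, "speed") - 1)
  list(r2_speed_fp_speedclamp = fp$speed,
       r2_speed_fp_fpclamp = fp$fp,
       r2_speed_fp_avg = fp$avg,
       r2_speed_fb_avg = fb$avg,
       r2_speed_stride_length_avg = sl$avg,
       r2_speed_stride_duration_avg = sd_$avg,
       r2_speed_net_power_avg = npv$avg,
       r2_fp_net_power_avg = npf$avg,
       r2_speed_cot_avg = cotv$avg,
       r2_fp_cot_avg = cotf$avg,
       speed_offset_pct = off("mean_speed"),
       fp_offset_pct = off("mean_fp"),
       np_offset_pct = off("net_power"),
       cot_offset_pct = off("cot"),
       n_trials = nrow(summaries))
}

#' Validate a run against the calibration targets
#'
#' Compares the statistics recovered from a completed run with the target
#' table at its stated tolerances and emits machine-readable verdicts.
#' Accepts a `fpclamp_run`, a summary table, or a run directory containing
#' `summaries.tsv`. A corrupted or missing summary table yields a failed
#' verdict table, not an error.
#'
#' @param x Run object, summary data.frame, or run directory path.
#' @param targets Target table, default [fpclamp_targets()].
#' @return data.frame: `metric`, `target`, `tol`, `value`, `pass`, `note`.
#' @export
validate_targets <- function(x, targets = fpclamp_targets()) {
  fail_all <- function(note) {
    data.frame(metric = targets$metric, target = targets$target,
               tol = targets$tol, value = NA_real_, pass = FALSE,
               note = note, stringsAsFactors = FALSE)
  }
  summaries <- tryCatch({
    if (inherits(x, "fpclamp_run")) x$summaries
    else if (is.data.frame(x)) x
    else if (is.character(x) && length(x) == 1) {
      f <- file.path(x, "summaries.tsv")
      if (!file.exists(f)) stop("missing summaries.tsv in run directory")
      data.table::fread(f, data.table = FALSE)
    } else stop("unsupported input")
  }, error = function(e) e)
  if (inherits(summaries, "error")) {
    return(fail_all(conditionMessage(summaries)))
  }
  m <- tryCatch(metrics_from_summaries(summaries), error = function(e) e)
  if (inherits(m, "error")) return(fail_all(conditionMessage(m)))
  out <- targets
  out$value <- vapply(targets$metric, function(k) {
    if (is.null(m[[k]])) NA_real_ else m[[k]]
  }, numeric(1))
  out$pass <- !is.na(out$value) & abs(out$value - out$target) <= out$tol
  out$note <- ifelse(is.na(out$value), "metric not computable", "")
  out
}

#' Acceptance metric set over multiple seeds
#'
#' Runs the default-scale experiment (20 participants, 5 intensities, both
#' clamps, 300 s trials at 100 Hz) once per seed and averages the recovered
#' statistics — the stochastic targets are defined as means over >= 10 seeds.
#' Child seeds are derived deterministically from `seed`.
#'
#' @param seed Root integer seed.
#' @param n_seeds Number of independent cohort runs.
#' @param n_participants,trial_duration,analog_rate Scale overrides (the
#'   defaults are the calibrated cohort scale).
#' @param quiet Suppress per-run progress.
#' @param keep_summaries Also return the first run's summary table
#'   (`first_summaries`), for downstream single-cohort checks.
#' @return List with `per_seed` (data.frame, one row of metrics per run),
#'   `mean` (named list of across-seed means) and `first_summaries`.
#' @export
acceptance_metrics <- function(seed = 1, n_seeds = 10, n_participants = 20,
                               trial_duration = 300, analog_rate = 100,
                               quiet = TRUE, keep_summaries = FALSE) {
  rows <- vector("list", n_seeds)
  first_summaries <- NULL
  for (s in seq_len(n_seeds)) {
    rc <- run_config(n_participants = n_participants,
                     trial_duration = trial_duration,
                     analog_rate = analog_rate,
                     seed = child_seed(seed, extra = s) %% 1000000L + s)
    run <- run_cohort(rc)
    if (s == 1 && keep_summaries) first_summaries <- run$summaries
    rows[[s]] <- as.data.frame(metrics_from_summaries(run$summaries))
    if (!quiet) message(sprintf("seed run %d/%d done", s, n_seeds))
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, mean = as.list(colMeans(per_seed)),
       first_summaries = first_summaries)
}
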