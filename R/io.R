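# Plain-text serialization: one columnar table per trial plus a breath table
# and a JSON metadata sidecar; YAML run configs.

intensity_label <- function(intensity) {
  if (is.na(intensity)) return("na")
  v <- round(100 * intensity)
  if (v == 0) "norm" else sprintf("%s%02d", if (v > 0) "p" else "m", abs(v))
}

#' Write a raw trial as columnar text
#'
#' Writes `<prefix>.tsv` (time, grfV_L, grfV_R, grfAP_L, grfAP_R, cop_ap,
#' heelAP_L, heelAP_R, belt_speed), `<prefix>_breaths.tsv` (t, vo2, vco2) and
#' `<prefix>_meta.json`.
#'
#' @param trial A `fpclamp_trial`.
#' @param dir Output directory (created if needed).
#' @return The file prefix, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "fpclamp_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- file.path(dir, paste(trial$participant_id, trial$clamp_type,
                                 intensity_label(trial$intensity), sep = "_"))
  ts <- data.table::data.table(
    time = trial$time,
    grfV_L = trial$grf_vertical_l, grfV_R = trial$grf_vertical_r,
    grfAP_L = trial$grf_ap_l, grfAP_R = trial$grf_ap_r,
    cop_ap = trial$cop_ap,
    heelAP_L = trial$heel_ap_l, heelAP_R = trial$heel_ap_r,
    belt_speed = trial$belt_speed)
  data.table::fwrite(ts, paste0(prefix, ".tsv"), sep = "\t")
  data.table::fwrite(trial$breaths, paste0(prefix, "_breaths.tsv"), sep = "\t")
  meta <- trial$meta
  meta$controller_trace <- NULL
  meta <- c(list(participant_id = trial$participant_id,
                 clamp_type = trial$clamp_type,
                 intensity = trial$intensity), meta)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' Read a raw trial written by [write_trial()]
#'
#' @param prefix File prefix (path without the `.tsv` / `_meta.json` suffix).
#' @return A `fpclamp_trial` object.
#' @export
read_trial <- function(prefix) {
  ts <- data.table::fread(paste0(prefix, ".tsv"), sep = "\t",
                          data.table = FALSE)
  breaths <- data.table::fread(paste0(prefix, "_breaths.tsv"), sep = "\t",
                               data.table = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(
    participant_id = meta$participant_id,
    clamp_type = meta$clamp_type,
    intensity = if (is.null(meta$intensity)) NA_real_ else meta$intensity,
    time = ts$time,
    grf_vertical_l = ts$grfV_L, grf_vertical_r = ts$grfV_R,
    grf_ap_l = ts$grfAP_L, grf_ap_r = ts$grfAP_R,
    cop_ap = ts$cop_ap,
    heel_ap_l = ts$heelAP_L, heel_ap_r = ts$heelAP_R,
    belt_speed = ts$belt_speed,
    breaths = breaths,
    meta = meta[setdiff(names(meta),
                        c("participant_id", "clamp_type", "intensity"))]
  ), class = "fpclamp_trial")
}

#' Save / load a run configuration as YAML
#'
#' The YAML mirrors the configuration lists; loading reconstitutes the
#' package objects, so `load_run_config(save_run_config(x, f))` reproduces
#' `x`.
#'
#' @param config A [run_config()] object.
#' @param path YAML file path.
#' @return `save_run_config`: `path` invisibly. `load_run_config`: the
#'   reconstructed `fpclamp_runconfig`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "fpclamp_runconfig"))
  plain <- list(
    cohort = config$cohort[c("n_participants", "intensities", "trial_duration",
                             "analysis_window", "packet_rate", "analog_rate",
                             "seed")],
    zero_noise = isTRUE(config$zero_noise),
    controller = config$controller,
    metabolic = config$metabolic,
    analysis = config$analysis
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  plain <- yaml::read_yaml(path)
  do.call(run_config, c(plain$cohort,
                        list(zero_noise = isTRUE(plain$zero_noise)),
                        plain$controller, plain$metabolic, plain$analysis))
}
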