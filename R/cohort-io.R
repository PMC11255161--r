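# Cohort export / import: one tidy measurements CSV plus a JSON sidecar
# holding the configuration and the true generating parameters (used by
# parameter-recovery tests).

#' Write a synthetic cohort to disk
#'
#' Writes `measurements.csv` (patient, cycle, region, kind, mass_g,
#' time_h, activity_MBq, injected_MBq) and `truth.json` (config, regions,
#' cycles, true kinetics) into `dir`.
#'
#' @param cohort An `rlt_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
cohort_write <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rlt_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"))
  sidecar <- list(
    config = unclass(cohort$config),
    regions = cohort$regions,
    cycles = cohort$cycles,
    truth = cohort$truth
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}

#' Read a synthetic cohort from disk
#'
#' Inverse of [cohort_write()]; restores an `rlt_cohort` from a directory
#' containing `measurements.csv` and `truth.json`.
#'
#' @param dir Directory written by [cohort_write()].
#' @return An `rlt_cohort`.
#' @export
cohort_read <- function(dir) {
  mpath <- file.path(dir, "measurements.csv")
  tpath <- file.path(dir, "truth.json")
  if (!file.exists(mpath) || !file.exists(tpath)) {
    abort(sprintf("'%s' does not contain measurements.csv + truth.json.", dir),
          class = "rlt_io_error")
  }
  measurements <- readr::read_csv(mpath, show_col_types = FALSE)
  side <- jsonlite::read_json(tpath, simplifyVector = TRUE)
  cfg_raw <- side$config
  cfg <- cohort_config(
    n_patients = cfg_raw$n_patients, n_cycles = cfg_raw$n_cycles,
    activity_mean_GBq = cfg_raw$activity_mean_GBq,
    activity_sd_GBq = cfg_raw$activity_sd_GBq,
    activity_range_GBq = unlist(cfg_raw$activity_range_GBq),
    early_schedule_h = unlist(cfg_raw$early_schedule_h),
    last_tp_choices_h = unlist(cfg_raw$last_tp_choices_h),
    last_tp_weights = unlist(cfg_raw$last_tp_weights),
    organ_kinetics = as_tibble(cfg_raw$organ_kinetics),
    lesion_kinetics = as_tibble(cfg_raw$lesion_kinetics),
    lesion_counts = unlist(cfg_raw$lesion_counts),
    lesion_cycle_counts = unlist(cfg_raw$lesion_cycle_counts),
    max_lesions_per_patient = cfg_raw$max_lesions_per_patient,
    lesion_model = cfg_raw$lesion_model,
    uptake_half_life_h = cfg_raw$uptake_half_life_h,
    intercycle_cv = cfg_raw$intercycle_cv, noise_cv = cfg_raw$noise_cv,
    kidney_volume_mean_ml = cfg_raw$kidney_volume_mean_ml,
    kidney_volume_cv = cfg_raw$kidney_volume_cv,
    lesion_volume_meanlog = cfg_raw$lesion_volume_meanlog,
    lesion_volume_sdlog = cfg_raw$lesion_volume_sdlog,
    seed = cfg_raw$seed
  )
  structure(
    list(config = cfg,
         regions = as_tibble(side$regions),
         cycles = as_tibble(side$cycles),
         truth = as_tibble(side$truth),
         measurements = measurements),
    class = "rlt_cohort"
  )
}
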