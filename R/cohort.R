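# Synthetic cohort generation.
#
# Virtual patients whose time-activity data reproduce the statistical
# structure of a 16-patient, 4-cycle Lu-177 PSMA therapy study: per-cycle
# normalized-dose and effective-half-life targets per region kind, with
# inter-patient (lognormal) and inter-cycle variability, declining tumor
# uptake with lesion dropout, and multiplicative measurement noise. The
# generator works backwards from the published summary statistics: the
# target normalized dose and half-life of each region are inverted into
# monoexponential (or uptake-biexponential) kinetics whose forward
# dosimetry returns the target exactly.

#' Per-cycle organ-at-risk kinetic targets
#'
#' Default normalized absorbed dose (mGy/MBq) and effective half-life (h)
#' targets, with between-patient SDs, for kidneys and salivary glands in
#' treatment cycles 1-4.
#'
#' @return A tibble with columns `kind`, `cycle`, `norm_dose_mean`,
#'   `norm_dose_sd`, `t_eff_mean`, `t_eff_sd`.
#' @export
default_organ_kinetics <- function() {
  tibble::tribble(
    ~kind,           ~cycle, ~norm_dose_mean, ~norm_dose_sd, ~t_eff_mean, ~t_eff_sd,
    "kidney",             1,            0.67,          0.30,        39.3,      13.7,
    "kidney",             2,            0.73,          0.29,        38.0,      14.6,
    "kidney",             3,            0.75,          0.33,        36.3,      13.6,
    "kidney",             4,            0.67,          0.36,        36.7,      16.3,
    "parotid",            1,            0.30,          0.18,        36.4,      13.0,
    "parotid",            2,            0.28,          0.06,        32.6,       8.2,
    "parotid",            3,            0.31,          0.10,        37.3,      16.7,
    "parotid",            4,            0.25,          0.09,        39.4,      18.2,
    "submandibular",      1,            0.23,          0.11,        41.6,      17.3,
    "submandibular",      2,            0.23,          0.08,        47.7,      19.8,
    "submandibular",      3,            0.23,          0.08,        44.6,      19.5,
    "submandibular",      4,            0.20,          0.06,        34.3,       8.5
  )
}

#' Per-cycle tumor-lesion kinetic targets
#'
#' Default per-cycle normalized-dose targets by lesion kind (bone vs soft
#' tissue, the latter covering lymph-node lesions and local recurrence)
#' and the cycle-1 effective-half-life distribution, held constant over
#' cycles (tumor dose declines through reduced uptake, not faster
#' clearance).
#'
#' @return A tibble with columns `kind`, `cycle`, `norm_dose_mean`,
#'   `norm_dose_sd`, `t_eff_mean`, `t_eff_sd`.
#' @export
default_lesion_kinetics <- function() {
  tibble::tribble(
    ~kind,         ~cycle, ~norm_dose_mean, ~norm_dose_sd, ~t_eff_mean, ~t_eff_sd,
    "lesion_bone",      1,            2.91,          2.52,        55.5,      19.2,
    "lesion_bone",      2,            1.91,          1.37,        55.5,      19.2,
    "lesion_bone",      3,            1.73,          1.07,        55.5,      19.2,
    "lesion_bone",      4,            1.65,          1.50,        55.5,      19.2,
    "lesion_soft",      1,            7.18,          3.94,        52.2,      13.5,
    "lesion_soft",      2,            3.98,          2.62,        52.2,      13.5,
    "lesion_soft",      3,            3.07,          3.13,        52.2,      13.5,
    "lesion_soft",      4,            3.36,          4.92,        52.2,      13.5
  )
}

#' Synthetic cohort configuration
#'
#' All knobs of the virtual study. Defaults emulate the study conditions:
#' 16 patients, 4 cycles, injected activity ~6.2 GBq (truncated normal,
#' range 5.0-6.7 GBq), imaging at 2/24/48 h plus a variable last time
#' point in 72-168 h with mean ~130 h, organ and lesion kinetics from
#' [default_organ_kinetics()] / [default_lesion_kinetics()], 90 lesions
#' (70 bone / 19 lymph node / 1 local recurrence, at most 10 per patient)
#' with per-cycle counts declining 90/87/79/67 through dropout.
#'
#' @param n_patients Number of patients.
#' @param n_cycles Number of treatment cycles per patient.
#' @param activity_mean_GBq,activity_sd_GBq,activity_range_GBq Truncated
#'   normal injected-activity distribution (GBq), per cycle.
#' @param early_schedule_h Fixed early imaging times (h).
#' @param last_tp_choices_h,last_tp_weights Last-time-point support and
#'   sampling weights (chosen to give mean ~130 h).
#' @param organ_kinetics,lesion_kinetics Per-kind, per-cycle target tables
#'   (see the two default functions for the schema).
#' @param lesion_counts Named counts `c(bone = , node = , local = )` for
#'   the whole cohort.
#' @param lesion_cycle_counts Number of analyzable lesions per cycle
#'   (non-increasing; lesions dropped in a cycle stay dropped). `NULL`
#'   scales the default 90/87/79/67 plan to `sum(lesion_counts)`.
#' @param max_lesions_per_patient Cap on lesions per patient.
#' @param lesion_model `"monoexp"` (default) or `"uptake_biexp"` for the
#'   true lesion kinetics; organs are monoexponential.
#' @param uptake_half_life_h Uptake half-life (h) used when
#'   `lesion_model = "uptake_biexp"`.
#' @param intercycle_cv Fractional inter-cycle kinetic variability applied
#'   multiplicatively to amplitude and organ half-life.
#' @param noise_cv Multiplicative lognormal measurement noise CV.
#' @param kidney_volume_mean_ml,kidney_volume_cv Combined (paired) kidney
#'   volume distribution; converted to mass with the kidney density.
#' @param lesion_volume_meanlog,lesion_volume_sdlog Lognormal lesion
#'   volume (ml) parameters.
#' @param seed Integer seed; every random draw of the generator flows
#'   from it.
#' @return A validated `cohort_config` object.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = 16,
                          n_cycles = 4,
                          activity_mean_GBq = 6.2,
                          activity_sd_GBq = 0.5,
                          activity_range_GBq = c(5.0, 6.7),
                          early_schedule_h = c(2, 24, 48),
                          last_tp_choices_h = c(72, 96, 120, 144, 168),
                          last_tp_weights = c(0.12, 0.15, 0.20, 0.24, 0.29),
                          organ_kinetics = default_organ_kinetics(),
                          lesion_kinetics = default_lesion_kinetics(),
                          lesion_counts = c(bone = 70, node = 19, local = 1),
                          lesion_cycle_counts = NULL,
                          max_lesions_per_patient = 10,
                          lesion_model = c("monoexp", "uptake_biexp"),
                          uptake_half_life_h = 1,
                          intercycle_cv = 0.10,
                          noise_cv = 0.05,
                          kidney_volume_mean_ml = 300,
                          kidney_volume_cv = 0.15,
                          lesion_volume_meanlog = log(3),
                          lesion_volume_sdlog = 0.8,
                          seed = 42L) {
  lesion_model <- match.arg(lesion_model)
  stopifnot(
    n_patients >= 1, n_cycles >= 1,
    activity_sd_GBq >= 0, length(activity_range_GBq) == 2,
    activity_range_GBq[1] < activity_range_GBq[2],
    all(diff(early_schedule_h) > 0), all(early_schedule_h > 0),
    length(last_tp_choices_h) == length(last_tp_weights),
    all(last_tp_weights >= 0), sum(last_tp_weights) > 0,
    min(last_tp_choices_h) > max(early_schedule_h),
    intercycle_cv >= 0, noise_cv >= 0,
    all(lesion_counts >= 0), uptake_half_life_h > 0
  )
  n_lesions <- sum(lesion_counts)
  if (n_lesions > n_patients * max_lesions_per_patient) {
    abort("lesion plan infeasible: more lesions than patient capacity.",
          class = "rlt_config_error")
  }
  if (is.null(lesion_cycle_counts)) {
    lesion_cycle_counts <- round(n_lesions * c(1, 87 / 90, 79 / 90, 67 / 90))
    lesion_cycle_counts <- lesion_cycle_counts[pmin(seq_len(n_cycles), 4)]
  }
  if (length(lesion_cycle_counts) != n_cycles ||
      any(diff(lesion_cycle_counts) > 0) ||
      (n_lesions > 0 && lesion_cycle_counts[1] != n_lesions)) {
    abort("`lesion_cycle_counts` must be non-increasing, length `n_cycles`, starting at the total lesion count.",
          class = "rlt_config_error")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_cycles = as.integer(n_cycles),
      activity_mean_GBq = activity_mean_GBq, activity_sd_GBq = activity_sd_GBq,
      activity_range_GBq = activity_range_GBq,
      early_schedule_h = early_schedule_h,
      last_tp_choices_h = last_tp_choices_h,
      last_tp_weights = last_tp_weights / sum(last_tp_weights),
      organ_kinetics = as_tibble(organ_kinetics),
      lesion_kinetics = as_tibble(lesion_kinetics),
      lesion_counts = lesion_counts,
      lesion_cycle_counts = as.integer(lesion_cycle_counts),
      max_lesions_per_patient = as.integer(max_lesions_per_patient),
      lesion_model = lesion_model, uptake_half_life_h = uptake_half_life_h,
      intercycle_cv = intercycle_cv, noise_cv = noise_cv,
      kidney_volume_mean_ml = kidney_volume_mean_ml,
      kidney_volume_cv = kidney_volume_cv,
      lesion_volume_meanlog = lesion_volume_meanlog,
      lesion_volume_sdlog = lesion_volume_sdlog,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# lognormal multiplier with mean 1 and the given CV
.rlnorm_mean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(mean, n))
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

#' Invert normalized-dose targets into true kinetics
#'
#' Solves for the kinetic parameters whose forward dosimetry (TIA, sphere
#' self-dose, division by injected activity) returns a requested
#' normalized dose exactly: the clearance rate is `log(2) / t_eff_h` and
#' the amplitude follows from
#' `TIA = norm_dose * injected_MBq / S(mass)` with `TIA = A0 / lambda_eff`
#' (monoexponential) or `TIA = A0 (1/lambda_eff - 1/lambda_up)` (uptake
#' biexponential).
#'
#' @param norm_dose_mGy_per_MBq Target normalized absorbed dose (> 0).
#' @param t_eff_h Target effective half-life in hours (> 0).
#' @param injected_MBq Injected activity (> 0).
#' @param region A [source_region()].
#' @param nuclide A [radionuclide()].
#' @param model `"monoexp"` or `"uptake_biexp"`.
#' @param uptake_half_life_h Uptake half-life for the biexponential model;
#'   must be shorter than `t_eff_h`.
#' @return A `true_kinetics` object (`model`, `amplitude_MBq`,
#'   `clearance_rate_h`, `uptake_rate_h`).
#' @export
kinetics_from_targets <- function(norm_dose_mGy_per_MBq, t_eff_h, injected_MBq,
                                  region, nuclide = radionuclide(),
                                  model = c("monoexp", "uptake_biexp"),
                                  uptake_half_life_h = 1) {
  model <- match.arg(model)
  if (norm_dose_mGy_per_MBq <= 0 || t_eff_h <= 0 || injected_MBq <= 0) {
    abort("targets must be positive.")
  }
  s <- self_dose_factor(region, nuclide)
  tia <- norm_dose_mGy_per_MBq * injected_MBq / s
  lam_eff <- decay_constant(t_eff_h)
  if (model == "monoexp") {
    a0 <- tia * lam_eff
    lam_up <- NA_real_
  } else {
    lam_up <- decay_constant(uptake_half_life_h)
    if (lam_up <= lam_eff) abort("uptake rate must exceed clearance rate.")
    a0 <- tia / (1 / lam_eff - 1 / lam_up)
  }
  if (a0 <= 0) abort("requested dose unreachable (non-positive amplitude).")
  structure(list(model = model, amplitude_MBq = a0, clearance_rate_h = lam_eff,
                 uptake_rate_h = lam_up),
            class = "true_kinetics")
}

# forward map: true curve evaluated at arbitrary times
.true_activity <- function(kin, time_h) {
  if (kin$model == "monoexp") {
    kin$amplitude_MBq * exp(-kin$clearance_rate_h * time_h)
  } else {
    kin$amplitude_MBq * (exp(-kin$clearance_rate_h * time_h) -
                           exp(-kin$uptake_rate_h * time_h))
  }
}

#' Simulate a measured time-activity curve
#'
#' Evaluates the true kinetic model at the schedule times and applies
#' i.i.d. multiplicative lognormal measurement noise with mean 1 and the
#' given CV. `noise_cv = 0` returns the exact curve.
#'
#' @param kin A `true_kinetics` object (see [kinetics_from_targets()]).
#' @param schedule_h Strictly increasing positive measurement times (h).
#' @param noise_cv Measurement noise CV (>= 0).
#' @param seed Optional integer seed for reproducible noise.
#' @return A tibble with columns `time_h`, `activity_MBq`.
#' @export
simulate_tac <- function(kin, schedule_h, noise_cv = 0.05, seed = NULL) {
  stopifnot(length(schedule_h) >= 1, all(schedule_h >= 0), all(diff(schedule_h) > 0))
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  if (!is.null(seed)) withr::local_seed(seed)
  a_true <- .true_activity(kin, schedule_h)
  tibble(time_h = schedule_h,
         activity_MBq = a_true * .rlnorm_mean1(length(schedule_h), noise_cv))
}

# assign lesions to patients, at most `cap` each
.assign_lesions <- function(n_lesions, n_patients, cap) {
  slots <- rep(seq_len(n_patients), each = cap)
  sample(slots)[seq_len(n_lesions)]
}

#' Generate a synthetic treatment cohort
#'
#' Draws a full virtual study from a [cohort_config()]: per-patient
#' regions (combined kidneys, parotid and submandibular glands, assigned
#' lesions), per-cycle injected activities and imaging schedules, true
#' kinetics per region and cycle (lognormal inter-patient spread around
#' the per-cycle targets with a patient/lesion-level random effect shared
#' across cycles, plus inter-cycle jitter), lesion dropout per the
#' per-cycle count plan, and noisy measured TACs.
#'
#' @param config A [cohort_config()].
#' @param nuclide A [radionuclide()].
#' @return An `rlt_cohort` object: list with tibbles `regions`, `cycles`,
#'   `truth` and `measurements`, plus the `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 2, lesion_counts = c(bone = 4), seed = 7))
#' coh
#' @export
generate_cohort <- function(config = cohort_config(), nuclide = radionuclide()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::local_seed(config$seed)
  np <- config$n_patients
  nc <- config$n_cycles
  pid <- sprintf("P%02d", seq_len(np))
  dens <- nuclide_defaults()$densities

  ## regions -----------------------------------------------------------
  kid_vol <- config$kidney_volume_mean_ml *
    .rlnorm_mean1(np, config$kidney_volume_cv)
  organs <- dplyr::bind_rows(
    tibble(patient_id = pid, region_id = paste0(pid, "_kidney"), kind = "kidney",
           lesion_type = NA_character_, volume_ml = kid_vol,
           density_g_per_ml = dens$kidney, mass_g = kid_vol * dens$kidney),
    tibble(patient_id = pid, region_id = paste0(pid, "_parotid"), kind = "parotid",
           lesion_type = NA_character_, volume_ml = NA_real_,
           density_g_per_ml = dens$soft_tissue,
           mass_g = nuclide_defaults()$gland_masses_g$parotid),
    tibble(patient_id = pid, region_id = paste0(pid, "_submandibular"),
           kind = "submandibular", lesion_type = NA_character_, volume_ml = NA_real_,
           density_g_per_ml = dens$soft_tissue,
           mass_g = nuclide_defaults()$gland_masses_g$submandibular)
  )
  lc <- config$lesion_counts
  n_les <- sum(lc)
  lesions <- NULL
  if (n_les > 0) {
    lesion_type <- rep(names(lc), lc)
    kind <- ifelse(lesion_type == "bone", "lesion_bone", "lesion_soft")
    owner <- .assign_lesions(n_les, np, config$max_lesions_per_patient)
    vol <- pmax(exp(stats::rnorm(n_les, config$lesion_volume_meanlog,
                                 config$lesion_volume_sdlog)), 0.3)
    density <- ifelse(kind == "lesion_bone", dens$bone_lesion, dens$soft_tissue_lesion)
    lesions <- tibble(
      patient_id = pid[owner],
      region_id = sprintf("L%03d_%s", seq_len(n_les), lesion_type),
      kind = kind, lesion_type = lesion_type, volume_ml = vol,
      density_g_per_ml = density, mass_g = vol * density
    )
  }
  regions <- dplyr::bind_rows(organs, lesions)

  ## cycles: injected activity and schedule ----------------------------
  cycles <- tidyr::expand_grid(patient_id = pid, cycle = seq_len(nc)) |>
    mutate(
      injected_MBq = 1000 * .rtruncnorm(dplyr::n(), config$activity_mean_GBq,
                                        config$activity_sd_GBq,
                                        config$activity_range_GBq[1],
                                        config$activity_range_GBq[2]),
      last_tp_h = sample(config$last_tp_choices_h, dplyr::n(), replace = TRUE,
                         prob = config$last_tp_weights)
    )

  ## lesion dropout plan (exact per-cycle counts, monotone) -------------
  present_tab <- NULL
  if (n_les > 0) {
    alive <- matrix(TRUE, nrow = n_les, ncol = nc)
    for (cy in seq_len(nc)[-1]) {
      surv <- which(alive[, cy - 1])
      n_drop <- length(surv) - config$lesion_cycle_counts[cy]
      if (n_drop > 0) {
        dropped <- sample(surv, n_drop)
        alive[dropped, cy:nc] <- FALSE
      } else {
        alive[, cy] <- alive[, cy - 1]
      }
    }
    present_tab <- tibble(
      region_id = rep(lesions$region_id, nc),
      cycle = rep(seq_len(nc), each = n_les),
      present = as.vector(alive)
    )
  }

  ## true kinetics per region x cycle -----------------------------------
  kin_targets <- dplyr::bind_rows(config$organ_kinetics, config$lesion_kinetics) |>
    mutate(
      dose_cv = ifelse(.data$norm_dose_mean > 0, .data$norm_dose_sd / .data$norm_dose_mean, 0),
      teff_cv = ifelse(.data$t_eff_mean > 0, .data$t_eff_sd / .data$t_eff_mean, 0)
    )
  # patient/lesion-level random effect: one multiplier per region for dose
  # and one for T_eff, with the kind's mean CV across cycles
  kind_cv <- kin_targets |>
    group_by(.data$kind) |>
    summarise(dose_cv = mean(.data$dose_cv), teff_cv = mean(.data$teff_cv))
  reg_eff <- regions |>
    left_join(kind_cv, by = "kind") |>
    mutate(
      u_dose = purrr::map_dbl(.data$dose_cv, ~ .rlnorm_mean1(1, .x)),
      u_teff = purrr::map_dbl(.data$teff_cv, ~ .rlnorm_mean1(1, .x))
    ) |>
    select("patient_id", "region_id", "kind", "mass_g", "u_dose", "u_teff")

  truth <- tidyr::expand_grid(
    reg_eff |> dplyr::rename(region_kind = "kind"),
    cycle = seq_len(nc)
  ) |>
    left_join(
      kin_targets |> select("kind", "cycle", "norm_dose_mean", "t_eff_mean"),
      by = c(region_kind = "kind", cycle = "cycle")
    ) |>
    left_join(cycles, by = c("patient_id", "cycle"))
  if (anyNA(truth$norm_dose_mean)) {
    abort("kinetic targets missing for some region kind x cycle; extend the kinetics tables.",
          class = "rlt_config_error")
  }
  is_lesion <- grepl("^lesion", truth$region_kind)
  n_rows <- nrow(truth)
  jit_dose <- .rlnorm_mean1(n_rows, config$intercycle_cv)
  jit_teff <- .rlnorm_mean1(n_rows, config$intercycle_cv)
  # lesion T_eff held constant across cycles (decline is uptake-driven)
  jit_teff[is_lesion] <- 1
  truth <- truth |>
    mutate(
      true_norm_dose = .data$norm_dose_mean * .data$u_dose * jit_dose,
      true_t_eff_h = .data$t_eff_mean * .data$u_teff * jit_teff,
      model = ifelse(is_lesion & config$lesion_model == "uptake_biexp",
                     "uptake_biexp", "monoexp")
    )
  if (!is.null(present_tab)) {
    truth <- truth |>
      left_join(present_tab, by = c("region_id", "cycle")) |>
      mutate(present = dplyr::coalesce(.data$present, TRUE))
  } else {
    truth <- truth |> mutate(present = TRUE)
  }
  truth <- truth |> filter(.data$present)

  kin_list <- purrr::pmap(
    list(truth$true_norm_dose, truth$true_t_eff_h, truth$injected_MBq,
         truth$mass_g, truth$model),
    function(d, teff, inj, m, mod) {
      kinetics_from_targets(d, teff, inj, list(mass_g = m), nuclide,
                            model = mod,
                            uptake_half_life_h = config$uptake_half_life_h)
    }
  )
  truth <- truth |>
    mutate(
      amplitude_MBq = purrr::map_dbl(kin_list, "amplitude_MBq"),
      clearance_rate_h = purrr::map_dbl(kin_list, "clearance_rate_h"),
      uptake_rate_h = purrr::map_dbl(kin_list, "uptake_rate_h")
    ) |>
    select("patient_id", "cycle", "region_id", region_kind = "region_kind",
           "mass_g", "injected_MBq", "last_tp_h", "model",
           "amplitude_MBq", "clearance_rate_h", "uptake_rate_h",
           "true_norm_dose", "true_t_eff_h")

  ## measurements -------------------------------------------------------
  measurements <- truth |>
    mutate(tac = purrr::pmap(
      list(.data$model, .data$amplitude_MBq, .data$clearance_rate_h,
           .data$uptake_rate_h, .data$last_tp_h),
      function(mod, a0, lam, lup, last_tp) {
        kin <- list(model = mod, amplitude_MBq = a0,
                    clearance_rate_h = lam, uptake_rate_h = lup)
        simulate_tac(kin, c(config$early_schedule_h, last_tp), config$noise_cv)
      }
    )) |>
    select("patient_id", "cycle", "region_id", kind = "region_kind",
           "mass_g", "injected_MBq", "tac") |>
    tidyr::unnest("tac")

  structure(
    list(config = config, regions = regions, cycles = cycles,
         truth = truth |> dplyr::rename(kind = "region_kind"),
         measurements = measurements),
    class = "rlt_cohort"
  )
}

#' @export
print.rlt_cohort <- function(x, ...) {
  nles <- sum(grepl("^lesion", x$regions$kind))
  cat(sprintf(
    "<rlt_cohort> %d patients x %d cycles, %d regions (%d lesions), %d measurements\n",
    x$config$n_patients, x$config$n_cycles, nrow(x$regions), nles,
    nrow(x$measurements)
  ))
  invisible(x)
}
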