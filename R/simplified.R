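# Simplified dosimetry methods.
#
# SM1 rescales the cycle-1 fitted TAC through a single measured time
# point in a later cycle (same pharmacokinetics assumed). SM2 and SM3
# extrapolate absorbed dose from the injected activity alone, using the
# normalized dose of cycle 1 (SM2) or the mean of cycles 1 and 2 (SM3).

.ORGAN_KINDS <- c("kidney", "parotid", "submandibular")
.TP_LABELS <- c("2-4h", "24h", "48h", "72-168h")
.SM1_T_MAX_H <- 400

#' Single-time-point dose (SM1)
#'
#' Assumes the pharmacokinetics of cycle 1 and rescales its fitted TAC
#' through one measured activity: with scale
#' `f = measured / A1_hat(t_single)` (the cycle-1 curve evaluated at the
#' observation time), the cycle's TIA is `f` times the cycle-1 TIA; dose
#' and normalized dose then follow as in the reference method, and the
#' effective half-life is inherited from cycle 1. A `trapezoid_tail`
#' cycle-1 fit is evaluated through its tail monoexponential (warning).
#'
#' @param ref_fit Cycle-1 `tac_fit` for the region.
#' @param obs A list/row with `t_single_h` (in (0, 400] h), `measured_MBq`
#'   (>= 0) and `injected_MBq` of the observed cycle.
#' @param region A [source_region()] (or list with `mass_g`).
#' @param nuclide A [radionuclide()].
#' @return One-row tibble with `tia_MBqh`, `dose_mGy`,
#'   `norm_dose_mGy_per_MBq` and the inherited `t_eff_h`.
#' @export
sm1_dose <- function(ref_fit, obs, region, nuclide = radionuclide()) {
  stopifnot(inherits(ref_fit, "tac_fit"))
  t <- obs$t_single_h
  if (!is.numeric(t) || t <= 0 || t > .SM1_T_MAX_H) {
    abort(sprintf("observation time must lie in (0, %d] h.", .SM1_T_MAX_H))
  }
  if (obs$measured_MBq < 0) abort("measured activity must be non-negative.")
  if (obs$injected_MBq <= 0) abort("injected activity must be positive.")
  a_hat <- predict_tac(ref_fit, t)
  if (!is.finite(a_hat) || a_hat <= 0) {
    abort("cycle-1 fitted activity non-positive at the observation time.")
  }
  f <- obs$measured_MBq / a_hat
  tia_i <- f * tia(ref_fit)
  dose <- absorbed_dose(tia_i, region, nuclide)
  tibble(tia_MBqh = tia_i, dose_mGy = dose,
         injected_MBq = obs$injected_MBq,
         norm_dose_mGy_per_MBq = dose / obs$injected_MBq,
         t_eff_h = ref_fit$t_eff_h)
}

#' Activity-scaled dose extrapolation from cycle 1 (SM2)
#'
#' \eqn{D_i = (D_1 / A_1) \times A_i}: the normalized dose of cycle 1
#' applied to the injected activity of cycle i.
#'
#' @param D1_mGy Cycle-1 absorbed dose (mGy).
#' @param A1_MBq Cycle-1 injected activity (> 0).
#' @param Ai_MBq Injected activity of the extrapolated cycle.
#' @return Absorbed dose in mGy.
#' @examples
#' sm2_dose(4000, 6200, 5000)
#' @export
sm2_dose <- function(D1_mGy, A1_MBq, Ai_MBq) {
  if (any(A1_MBq <= 0)) abort("`A1_MBq` must be positive.")
  (D1_mGy / A1_MBq) * Ai_MBq
}

#' Activity-scaled dose extrapolation from cycles 1 and 2 (SM3)
#'
#' \eqn{D_i = \frac{(D_1/A_1 + D_2/A_2)}{2} \times A_i}: the mean
#' normalized dose of the first two cycles applied to the injected
#' activity of cycle i.
#'
#' @param D1_mGy,A1_MBq Cycle-1 absorbed dose and injected activity.
#' @param D2_mGy,A2_MBq Cycle-2 absorbed dose and injected activity.
#' @param Ai_MBq Injected activity of the extrapolated cycle.
#' @return Absorbed dose in mGy.
#' @export
sm3_dose <- function(D1_mGy, A1_MBq, D2_mGy, A2_MBq, Ai_MBq) {
  if (any(A1_MBq <= 0) || any(A2_MBq <= 0)) {
    abort("`A1_MBq` and `A2_MBq` must be positive.")
  }
  ((D1_mGy / A1_MBq + D2_mGy / A2_MBq) / 2) * Ai_MBq
}

#' Run a simplified dosimetry method over a cohort
#'
#' Produces a dose-record table comparable to the reference method:
#'
#' * `SM1`: for cycles 2 onward, each region's dose is obtained from a
#'   single measured time point ([sm1_dose()]) at the chosen imaging time
#'   (`tp`); for `"72-168h"` the cycle's own last scan time is used.
#'   Applies to organs at risk and lesions.
#' * `SM2` / `SM3`: organ-at-risk doses for later cycles extrapolated
#'   from injected activity alone ([sm2_dose()], [sm3_dose()]). Refused
#'   for lesion regions: tumor uptake declines over cycles, which the
#'   extrapolation cannot reflect.
#'
#' Cycle-1 (and, for SM3, cycle-2) records are copied from the reference
#' method so cumulated totals are comparable.
#'
#' @param cohort An `rlt_cohort`.
#' @param rm_records Reference-method records from
#'   [run_reference_dosimetry()] on the same cohort.
#' @param method `"SM1"`, `"SM2"` or `"SM3"`.
#' @param tp Single-time-point label for SM1: one of `"2-4h"`, `"24h"`,
#'   `"48h"`, `"72-168h"`.
#' @param kinds Region kinds to process; defaults to all kinds for SM1
#'   and organs at risk for SM2/SM3.
#' @param nuclide A [radionuclide()].
#' @return A dose-record tibble with `method` and (for SM1) `tp_label`
#'   columns.
#' @export
run_simplified <- function(cohort, rm_records, method = c("SM1", "SM2", "SM3"),
                           tp = "48h", kinds = NULL, nuclide = radionuclide()) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "rlt_cohort"))
  rm_records <- as_tibble(rm_records)
  if (method == "SM1") {
    return(.run_sm1(cohort, rm_records, tp, kinds %||% unique(rm_records$kind), nuclide))
  }
  kinds <- kinds %||% .ORGAN_KINDS
  if (any(grepl("^lesion", kinds))) {
    abort(paste("SM2/SM3 cannot be applied to tumor lesions: uptake (and thus",
                "normalized dose) declines over treatment cycles, which an",
                "injected-activity extrapolation cannot reflect."),
          class = "rlt_method_error")
  }
  n_ref <- if (method == "SM2") 1L else 2L
  ref <- rm_records |>
    filter(.data$kind %in% kinds, .data$cycle <= n_ref)
  per_region_ref <- ref |>
    group_by(.data$patient_id, .data$region_id, .data$kind, .data$mass_g) |>
    summarise(norm_ref = mean(.data$dose_mGy / .data$injected_MBq),
              n_ref_cycles = dplyr::n(), .groups = "drop")
  if (any(per_region_ref$n_ref_cycles < n_ref)) {
    abort(sprintf("reference-method records for cycles 1..%d required for %s.",
                  n_ref, method), class = "rlt_method_error")
  }
  extrap <- cohort$cycles |>
    filter(.data$cycle > n_ref) |>
    dplyr::inner_join(per_region_ref, by = "patient_id",
                      relationship = "many-to-many") |>
    mutate(
      method = method, model = NA_character_,
      amplitude_MBq = NA_real_, clearance_rate_h = NA_real_,
      uptake_rate_h = NA_real_, t_eff_h = NA_real_,
      fit_residual_rms = NA_real_,
      dose_mGy = .data$norm_ref * .data$injected_MBq,
      tia_MBqh = .data$dose_mGy / self_dose_factor(.data$mass_g, nuclide),
      norm_dose_mGy_per_MBq = .data$norm_ref
    ) |>
    select(dplyr::any_of(names(rm_records)), "method")
  copied <- ref |> mutate(method = .env$method)
  dplyr::bind_rows(copied, extrap) |>
    dplyr::arrange(.data$patient_id, .data$region_id, .data$cycle)
}

.run_sm1 <- function(cohort, rm_records, tp, kinds, nuclide) {
  tp <- match.arg(tp, .TP_LABELS)
  ref1 <- rm_records |> filter(.data$cycle == 1, .data$kind %in% kinds)
  if (nrow(ref1) == 0) {
    abort("cycle-1 reference records required for SM1.", class = "rlt_method_error")
  }
  # single observation per (patient, cycle>=2, region): the tp-th scan,
  # or the cycle's own last scan for the 72-168 h window
  obs <- cohort$measurements |>
    filter(.data$cycle > 1, .data$kind %in% kinds) |>
    group_by(.data$patient_id, .data$cycle, .data$region_id, .data$kind,
             .data$mass_g, .data$injected_MBq) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    summarise(
      t_single_h = switch(tp,
        "2-4h" = .data$time_h[1], "24h" = .data$time_h[2],
        "48h" = .data$time_h[3], "72-168h" = .data$time_h[dplyr::n()]),
      measured_MBq = switch(tp,
        "2-4h" = .data$activity_MBq[1], "24h" = .data$activity_MBq[2],
        "48h" = .data$activity_MBq[3], "72-168h" = .data$activity_MBq[dplyr::n()]),
      .groups = "drop"
    ) |>
    dplyr::inner_join(
      ref1 |>
        select("region_id", ref_model = "model",
               ref_amplitude = "amplitude_MBq", ref_lambda = "clearance_rate_h",
               ref_lambda_up = "uptake_rate_h", ref_t_eff = "t_eff_h",
               ref_tia = "tia_MBqh"),
      by = "region_id"
    )
  if (any(obs$ref_model == "trapezoid_tail")) {
    warn("cycle-1 trapezoid-tail fit(s) evaluated via their tail monoexponential for SM1.")
  }
  a_hat <- ifelse(
    obs$ref_model == "uptake_biexp",
    obs$ref_amplitude * (exp(-obs$ref_lambda * obs$t_single_h) -
                           exp(-obs$ref_lambda_up * obs$t_single_h)),
    obs$ref_amplitude * exp(-obs$ref_lambda * obs$t_single_h)
  )
  if (any(!is.finite(a_hat) | a_hat <= 0)) {
    abort("cycle-1 fitted activity non-positive at an observation time.")
  }
  if (any(obs$t_single_h <= 0 | obs$t_single_h > .SM1_T_MAX_H)) {
    abort(sprintf("observation times must lie in (0, %d] h.", .SM1_T_MAX_H))
  }
  sm1 <- obs |>
    mutate(
      method = "SM1", model = .data$ref_model,
      amplitude_MBq = NA_real_, clearance_rate_h = .data$ref_lambda,
      uptake_rate_h = .data$ref_lambda_up, t_eff_h = .data$ref_t_eff,
      fit_residual_rms = NA_real_,
      tia_MBqh = .data$measured_MBq / a_hat * .data$ref_tia,
      dose_mGy = absorbed_dose(.data$tia_MBqh, .data$mass_g, nuclide),
      norm_dose_mGy_per_MBq = .data$dose_mGy / .data$injected_MBq
    ) |>
    select(dplyr::any_of(names(rm_records)), "method")
  dplyr::bind_rows(ref1 |> mutate(method = "SM1"), sm1) |>
    mutate(tp_label = tp) |>
    dplyr::arrange(.data$patient_id, .data$region_id, .data$cycle)
}
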