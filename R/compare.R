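# Agreement between simplified and reference dosimetry: Bland-Altman
# percent bias with 1.96*SD limits of agreement, RMSE, per-cycle
# deviation summaries, and a permutation-based between-cycle test.

#' Percent difference between paired dose estimates
#'
#' `100 * (d_SM - d_RM) / d_RM` by default (the reference method as
#' denominator), or the Bland-Altman mean-of-pair denominator.
#'
#' @param d_SM,d_RM Paired dose estimates in identical units.
#' @param denominator `"rm"` (default) or `"mean"`.
#' @return Percent differences.
#' @export
percent_difference <- function(d_SM, d_RM, denominator = c("rm", "mean")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "rm") d_RM else (d_SM + d_RM) / 2
  if (any(den <= 0)) abort("percent difference undefined for non-positive denominator.")
  100 * (d_SM - d_RM) / den
}

#' Root mean square error of paired estimates
#'
#' \eqn{\sqrt{\sum_k (d_{k,SM} - d_{k,RM})^2 / n}} in the input units.
#'
#' @inheritParams percent_difference
#' @return RMSE (scalar).
#' @export
rmse <- function(d_SM, d_RM) {
  if (length(d_SM) == 0) abort("rmse needs at least one pair.")
  stopifnot(length(d_SM) == length(d_RM))
  sqrt(mean((d_SM - d_RM)^2))
}

#' Bland-Altman agreement analysis
#'
#' Mean percent bias and 1.96 x sample-SD limits of agreement (which
#' contain ~95% of the percent differences), plus the RMSE in the input
#' units.
#'
#' @param pairs Data frame with columns `d_SM` and `d_RM` (see
#'   [comparison_pairs()]), or a numeric vector of SM values (then `d_RM`
#'   must be given).
#' @param d_RM Reference values when `pairs` is a vector.
#' @param denominator Passed to [percent_difference()].
#' @return A `ba_result` object: `n`, `bias_pct`, `sd_pct`, `loa_pct`
#'   (1.96 x SD), `loa_low_pct`, `loa_high_pct`, `rmse`.
#' @examples
#' bland_altman(c(1.1, 0.9, 1.0), c(1, 1, 1))
#' @export
bland_altman <- function(pairs, d_RM = NULL, denominator = c("rm", "mean")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(pairs)) {
    stopifnot(all(c("d_SM", "d_RM") %in% names(pairs)))
    d_sm <- pairs$d_SM
    d_rm <- pairs$d_RM
  } else {
    d_sm <- pairs
    d_rm <- d_RM
  }
  if (length(d_sm) < 2) abort("Bland-Altman needs >= 2 pairs.")
  pct <- percent_difference(d_sm, d_rm, denominator)
  bias <- mean(pct)
  sd_pct <- stats::sd(pct)
  loa <- 1.96 * sd_pct
  structure(
    list(n = length(pct), bias_pct = bias, sd_pct = sd_pct, loa_pct = loa,
         loa_low_pct = bias - loa, loa_high_pct = bias + loa,
         rmse = rmse(d_sm, d_rm), denominator = denominator,
         pairs = tibble(d_SM = d_sm, d_RM = d_rm, pct_diff = pct)),
    class = "ba_result"
  )
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf(
    "<ba_result> n = %d: bias %.2f%% +/- %.1f (LoA %.1f to %.1f), RMSE %.4g\n",
    x$n, x$bias_pct, x$loa_pct, x$loa_low_pct, x$loa_high_pct, x$rmse
  ))
  invisible(x)
}

#' @export
tidy.ba_result <- function(x, ...) {
  tibble(
    n = x$n, bias_pct = x$bias_pct, sd_pct = x$sd_pct, loa_pct = x$loa_pct,
    loa_low_pct = x$loa_low_pct, loa_high_pct = x$loa_high_pct, rmse = x$rmse
  )
}

#' @export
glance.ba_result <- tidy.ba_result

#' Pair simplified and reference dose records
#'
#' Inner-joins two dose-record tables on patient, region and cycle and
#' returns the paired values; errors (listing the offending keys) when
#' rows of the simplified table have no reference counterpart.
#'
#' @param sm_records,rm_records Dose-record tibbles.
#' @param value Column to compare (default normalized dose).
#' @param cycles Optional cycles to keep (e.g. `2:4` to compare only the
#'   cycles a single-time-point method actually estimates).
#' @return A tibble with the key columns, `d_SM` and `d_RM`.
#' @export
comparison_pairs <- function(sm_records, rm_records,
                             value = "norm_dose_mGy_per_MBq", cycles = NULL) {
  keys <- c("patient_id", "region_id", "cycle")
  sm <- as_tibble(sm_records)
  rm_ <- as_tibble(rm_records)
  stopifnot(value %in% names(sm), value %in% names(rm_))
  if (!is.null(cycles)) {
    sm <- sm |> filter(.data$cycle %in% cycles)
    rm_ <- rm_ |> filter(.data$cycle %in% cycles)
  }
  joined <- sm |>
    select(all_of(keys), dplyr::any_of("kind"), d_SM = all_of(value)) |>
    left_join(rm_ |> select(all_of(keys), d_RM = all_of(value)), by = keys)
  if (anyNA(joined$d_RM)) {
    bad <- joined |> filter(is.na(.data$d_RM)) |>
      mutate(key = paste(.data$patient_id, .data$region_id, .data$cycle, sep = "/"))
    abort(paste0("no reference record for: ",
                 paste(utils::head(bad$key, 10), collapse = ", "),
                 if (nrow(bad) > 10) sprintf(" (+%d more)", nrow(bad) - 10) else ""),
          class = "rlt_key_error")
  }
  joined
}

#' Per-cycle deviation from the first treatment cycle
#'
#' For each patient/region with a cycle-1 record, the percent deviation
#' of later-cycle normalized dose from cycle 1, plus across-patient means
#' by region kind and cycle. Patients/regions without a cycle-1 record
#' are excluded with a message.
#'
#' @param rm_records Reference-method dose records.
#' @return List with `deviations` (per patient/region/cycle) and
#'   `by_kind` (mean deviation per kind and cycle).
#' @export
cycle_deviation_summary <- function(rm_records) {
  rec <- as_tibble(rm_records)
  base <- rec |> filter(.data$cycle == 1) |>
    select("patient_id", "region_id", base_dose = "norm_dose_mGy_per_MBq")
  missing_base <- setdiff(unique(rec$region_id), base$region_id)
  if (length(missing_base) > 0) {
    rlang::inform(sprintf("excluding %d region(s) without a cycle-1 record.",
                          length(missing_base)))
  }
  dev <- rec |>
    filter(.data$cycle > 1) |>
    dplyr::inner_join(base, by = c("patient_id", "region_id")) |>
    mutate(pct_dev_from_cycle1 =
             100 * (.data$norm_dose_mGy_per_MBq - .data$base_dose) / .data$base_dose) |>
    select("patient_id", "region_id", "kind", "cycle", "pct_dev_from_cycle1")
  by_kind <- dev |>
    group_by(.data$kind, .data$cycle) |>
    summarise(n = dplyr::n(),
              mean_pct_dev = mean(.data$pct_dev_from_cycle1),
              sd_pct_dev = stats::sd(.data$pct_dev_from_cycle1),
              .groups = "drop")
  list(deviations = dev, by_kind = by_kind)
}

#' Permutation test for a between-cycle effect
#'
#' A repeated-measures permutation test of whether normalized dose (or
#' effective half-life) differs between treatment cycles: the statistic
#' is the variance of the per-cycle means of per-region values, and the
#' null distribution is built by permuting cycle labels within each
#' patient/region (missing cells allowed). This is a design-based
#' alternative to a parametric mixed-effects repeated-measures model;
#' exact p-values differ from such a model's.
#'
#' @param rm_records Reference-method dose records.
#' @param region_kind Kind(s) to test (e.g. `"kidney"`, or both lesion
#'   kinds).
#' @param value Column tested, default `"norm_dose_mGy_per_MBq"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed (deterministic p-value).
#' @return The permutation p-value.
#' @export
between_cycle_test <- function(rm_records, region_kind,
                               value = "norm_dose_mGy_per_MBq",
                               n_perm = 2000, seed = 1) {
  rec <- as_tibble(rm_records) |> filter(.data$kind %in% region_kind)
  stopifnot(value %in% names(rec))
  cycles <- sort(unique(rec$cycle))
  if (length(cycles) < 2) abort("between-cycle test needs >= 2 cycles.")
  if (dplyr::n_distinct(rec$patient_id) < 3) abort("need >= 3 patients.")
  wide <- rec |>
    select("region_id", "cycle", v = all_of(value)) |>
    tidyr::pivot_wider(names_from = "cycle", values_from = "v") |>
    select(-"region_id") |>
    as.matrix()
  stat <- function(m) stats::var(colMeans(m, na.rm = TRUE))
  obs <- stat(wide)
  withr::local_seed(seed)
  perm_stats <- replicate(n_perm, {
    m <- wide
    for (i in seq_len(nrow(m))) {
      ok <- which(!is.na(m[i, ]))
      if (length(ok) > 1) m[i, ok] <- m[i, sample(ok)]
    }
    stat(m)
  })
  (1 + sum(perm_stats >= obs - 1e-15)) / (1 + n_perm)
}

#' Table of single-time-point agreement by region group
#'
#' Runs SM1 at each requested imaging time point, compares it to the
#' reference method over cycles 2 onward, and summarises Bland-Altman
#' bias, limits of agreement and RMSE per region group. Lesions are
#' analyzed both per individual lesion and as the mean lesion dose per
#' patient.
#'
#' @param cohort An `rlt_cohort`.
#' @param rm_records Records from [run_reference_dosimetry()].
#' @param tps Time-point labels to evaluate.
#' @param denominator Passed to [percent_difference()].
#' @return A tibble with one row per region group x time point:
#'   `bias_pct`, `loa_pct`, `loa_low_pct`, `loa_high_pct`, `rmse`.
#' @export
sm1_comparison_table <- function(cohort, rm_records,
                                 tps = c("2-4h", "24h", "48h", "72-168h"),
                                 denominator = "rm") {
  rm_records <- as_tibble(rm_records)
  cmp_cycles <- 2:cohort$config$n_cycles
  purrr::map_dfr(tps, function(tp) {
    sm <- run_simplified(cohort, rm_records, method = "SM1", tp = tp)
    pairs <- comparison_pairs(sm, rm_records, cycles = cmp_cycles)
    groups <- list(
      kidneys = pairs |> filter(.data$kind == "kidney"),
      parotid = pairs |> filter(.data$kind == "parotid"),
      submandibular = pairs |> filter(.data$kind == "submandibular"),
      lesions_individual = pairs |> filter(grepl("^lesion", .data$kind)),
      lesions_patient_mean = pairs |>
        filter(grepl("^lesion", .data$kind)) |>
        group_by(.data$patient_id, .data$cycle) |>
        summarise(d_SM = mean(.data$d_SM), d_RM = mean(.data$d_RM),
                  .groups = "drop")
    )
    purrr::imap_dfr(groups, function(g, name) {
      if (nrow(g) < 2) return(NULL)
      tidy(bland_altman(g, denominator = denominator)) |>
        mutate(group = name, tp_label = tp, .before = 1)
    })
  })
}

#' Check a comparison JSON export against the shipped schema
#'
#' Structural validation of the JSON written by [dosim_compare()]:
#' required fields, types and limit-of-agreement consistency, following
#' `inst/extdata/comparison-schema.json`.
#'
#' @param path Path to a comparison JSON file.
#' @return `TRUE` (invisibly) if valid; otherwise an error.
#' @export
validate_comparison_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("method", "tp_label", "group", "n", "bias_pct", "loa_pct",
            "loa_low_pct", "loa_high_pct", "rmse")
  tab <- x$comparisons
  if (is.null(tab) || !all(need %in% names(tab))) {
    abort(sprintf("comparison JSON missing fields: %s",
                  paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  num <- c("n", "bias_pct", "loa_pct", "loa_low_pct", "loa_high_pct", "rmse")
  for (f in num) {
    if (!is.numeric(tab[[f]])) abort(sprintf("field '%s' must be numeric.", f))
  }
  if (any(abs((tab$bias_pct - tab$loa_pct) - tab$loa_low_pct) > 1e-6) ||
      any(abs((tab$bias_pct + tab$loa_pct) - tab$loa_high_pct) > 1e-6)) {
    abort("limits of agreement inconsistent with bias +/- loa.")
  }
  invisible(TRUE)
}
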