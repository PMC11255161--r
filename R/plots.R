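# ggplot2 visualisations for cohorts, dose records and agreement results.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_hline autoplot
#'   labs facet_wrap scale_y_log10 geom_boxplot theme_minimal
NULL

#' Plot measured time-activity curves
#'
#' @param object An `rlt_cohort`.
#' @param kinds Region kinds to show.
#' @param patients Optional subset of patient ids.
#' @param ... Unused.
#' @return A ggplot: activity vs time per region, faceted by kind.
#' @export
autoplot.rlt_cohort <- function(object, kinds = NULL, patients = NULL, ...) {
  d <- object$measurements
  if (!is.null(kinds)) d <- d |> filter(.data$kind %in% kinds)
  if (!is.null(patients)) d <- d |> filter(.data$patient_id %in% patients)
  ggplot(d, aes(x = .data$time_h, y = .data$activity_MBq,
                group = interaction(.data$region_id, .data$cycle),
                colour = factor(.data$cycle))) +
    geom_line(alpha = 0.4) + geom_point(size = 0.8) +
    scale_y_log10() +
    facet_wrap(~kind, scales = "free_y") +
    labs(x = "time post-injection (h)", y = "activity (MBq)",
         colour = "cycle") +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' Percent difference against the reference value, with the mean bias
#' and 1.96 SD limits of agreement.
#'
#' @param object A `ba_result` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_result <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$d_RM, y = .data$pct_diff)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = object$bias_pct, colour = "darkgreen") +
    geom_hline(yintercept = c(object$loa_low_pct, object$loa_high_pct),
               colour = "red", linetype = "dashed") +
    labs(x = "reference-method dose", y = "difference (%)",
         title = sprintf("bias %.2f%%, LoA [%.1f, %.1f]%%",
                         object$bias_pct, object$loa_low_pct,
                         object$loa_high_pct)) +
    theme_minimal()
}

#' @rdname autoplot.ba_result
#' @param x A `ba_result`.
#' @param y Unused.
#' @export
plot.ba_result <- function(x, y, ...) print(autoplot(x, ...))

#' Normalized dose by cycle
#'
#' Box plots of normalized absorbed dose per treatment cycle, faceted by
#' region kind.
#'
#' @param records A dose-record tibble.
#' @return A ggplot.
#' @export
plot_dose_by_cycle <- function(records) {
  ggplot(as_tibble(records),
         aes(x = factor(.data$cycle), y = .data$norm_dose_mGy_per_MBq)) +
    geom_boxplot(outlier.size = 0.7) +
    facet_wrap(~kind, scales = "free_y") +
    labs(x = "treatment cycle", y = "normalized dose (mGy/MBq)") +
    theme_minimal()
}
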