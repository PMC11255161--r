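# Time-activity-curve fitting and time-integrated activity (TIA).
#
# The reference dosimetry workflow fits each TAC with a monoexponential
# A0 exp(-lambda t) or an uptake biexponential A0 (exp(-lambda_eff t) -
# exp(-lambda_up t)) and integrates analytically to infinity. Where no
# exponential describes the data, trapezoidal integration with a
# monoexponential tail extrapolation is used instead.

# clearance-rate bounds: T_eff restricted to [0.5, 1000] h
.LAMBDA_MIN <- log(2) / 1000
.LAMBDA_MAX <- log(2) / 0.5
# a fit whose residual RMS exceeds this fraction of the peak activity is
# rejected and the TAC falls through to trapezoid + tail integration
.RESIDUAL_FRACTION_MAX <- 0.20

.fit_error <- function(msg) abort(msg, class = "rlt_fit_error")

.check_tac <- function(data) {
  stopifnot(is.data.frame(data), all(c("time_h", "activity_MBq") %in% names(data)))
  data <- dplyr::arrange(as_tibble(data), .data$time_h)
  if (any(data$time_h <= 0)) .fit_error("TAC times must be positive.")
  if (anyDuplicated(data$time_h)) .fit_error("TAC times must be distinct.")
  if (any(data$activity_MBq < 0)) .fit_error("TAC activities must be non-negative.")
  data
}

.new_tac_fit <- function(model, amplitude_MBq, clearance_rate_h,
                         uptake_rate_h = NA_real_, tail_points_used = NA_integer_,
                         fit_residual_rms = NA_real_, flagged = FALSE,
                         n_points = NA_integer_, tia_MBqh = NA_real_) {
  structure(
    list(model = model, amplitude_MBq = amplitude_MBq,
         clearance_rate_h = clearance_rate_h, uptake_rate_h = uptake_rate_h,
         t_eff_h = log(2) / clearance_rate_h,
         tail_points_used = tail_points_used,
         fit_residual_rms = fit_residual_rms, flagged = flagged,
         n_points = n_points, tia_MBqh = tia_MBqh),
    class = "tac_fit"
  )
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("<tac_fit> %s: A0 = %.4g MBq, T_eff = %.3g h%s%s\n",
              x$model, x$amplitude_MBq, x$t_eff_h,
              if (is.finite(x$uptake_rate_h)) sprintf(", T_up = %.3g h", log(2) / x$uptake_rate_h) else "",
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

# closed-form optimal amplitude for a fixed shape function s(t)
.optimal_amplitude <- function(activity, shape) {
  denom <- sum(shape^2)
  if (denom <= 0) return(0)
  max(sum(activity * shape) / denom, 0)
}

.residual_rms <- function(activity, fitted) sqrt(mean((activity - fitted)^2))

#' Fit a monoexponential time-activity curve
#'
#' Least squares on untransformed activities of \eqn{A_0 e^{-\lambda t}}.
#' Two points are solved log-linearly (exact); three or more points use
#' bounded Levenberg-Marquardt with a log-linear initial estimate. The
#' clearance rate is constrained to effective half-lives between 0.5 h and
#' 1000 h; a solution pinned at a bound (e.g. non-decaying data) is
#' returned with `flagged = TRUE`.
#'
#' @param data Data frame with columns `time_h` (> 0, distinct) and
#'   `activity_MBq` (>= 0); at least two positive activities required.
#' @return A `tac_fit` object (model `"monoexp"`).
#' @examples
#' tac <- data.frame(time_h = c(2, 24, 48, 120),
#'                   activity_MBq = 100 * exp(-log(2) / 50 * c(2, 24, 48, 120)))
#' fit_monoexp(tac)
#' @export
fit_monoexp <- function(data) {
  data <- .check_tac(data)
  pos <- data$activity_MBq > 0
  if (sum(pos) < 2) .fit_error("monoexponential fit needs >= 2 positive activities.")
  t <- data$time_h
  a <- data$activity_MBq
  # log-linear initialization on positive points
  lf <- stats::lm.fit(cbind(1, t[pos]), log(a[pos]))
  lam0 <- min(max(-lf$coefficients[2], .LAMBDA_MIN), .LAMBDA_MAX)
  if (nrow(data) == 2) {
    lam <- lam0
  } else {
    a0_init <- max(exp(lf$coefficients[1]), max(a) * 1e-3)
    res_fun <- function(p) a - p[1] * exp(-p[2] * t)
    nl <- minpack.lm::nls.lm(
      par = c(a0_init, lam0), fn = res_fun,
      lower = c(1e-12, .LAMBDA_MIN), upper = c(Inf, .LAMBDA_MAX),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    lam <- nl$par[2]
  }
  shape <- exp(-lam * t)
  a0 <- .optimal_amplitude(a, shape)
  flagged <- lam <= .LAMBDA_MIN * (1 + 1e-6) || lam >= .LAMBDA_MAX * (1 - 1e-6)
  .new_tac_fit("monoexp", a0, lam,
               fit_residual_rms = .residual_rms(a, a0 * shape),
               flagged = flagged, n_points = nrow(data))
}

#' Fit an uptake biexponential time-activity curve
#'
#' Least squares on untransformed activities of
#' \eqn{A_0 (e^{-\lambda_{eff} t} - e^{-\lambda_{up} t})} with
#' \eqn{\lambda_{up} > \lambda_{eff}}, for TACs whose activity still rises
#' at the first scan. Initialized from a monoexponential fit of the
#' post-peak points and an uptake half-life of 1 h. Fails (so the caller
#' can fall back) when the peak is at the first sample, fewer than four
#' points are available, or the fitted rates are nearly degenerate
#' (ratio < 1.05).
#'
#' @inheritParams fit_monoexp
#' @return A `tac_fit` object (model `"uptake_biexp"`).
#' @export
fit_uptake_biexp <- function(data) {
  data <- .check_tac(data)
  if (nrow(data) < 4) .fit_error("uptake biexponential fit needs >= 4 points.")
  t <- data$time_h
  a <- data$activity_MBq
  ipk <- which.max(a)
  if (ipk == 1) .fit_error("peak at first sample; use a monoexponential fit.")
  init <- fit_monoexp(data[ipk:nrow(data), , drop = FALSE])
  lam_up0 <- max(log(2) / 1, 2 * init$clearance_rate_h)
  res_fun <- function(p) {
    shape <- exp(-p[2] * t) - exp(-p[3] * t)
    a - p[1] * pmax(shape, 0)
  }
  nl <- tryCatch(
    minpack.lm::nls.lm(
      par = c(init$amplitude_MBq, init$clearance_rate_h, lam_up0), fn = res_fun,
      lower = c(1e-12, .LAMBDA_MIN, .LAMBDA_MIN),
      upper = c(Inf, .LAMBDA_MAX, log(2) / 0.01),
      control = minpack.lm::nls.lm.control(maxiter = 400)
    ),
    error = function(e) .fit_error(paste("biexponential fit failed:", conditionMessage(e)))
  )
  p <- nl$par
  if (p[3] < p[2]) p[c(2, 3)] <- p[c(3, 2)] # enforce lambda_up > lambda_eff
  if (p[3] / p[2] < 1.05) .fit_error("uptake and clearance rates degenerate (ratio < 1.05).")
  shape <- exp(-p[2] * t) - exp(-p[3] * t)
  a0 <- .optimal_amplitude(a, shape)
  .new_tac_fit("uptake_biexp", a0, p[2], uptake_rate_h = p[3],
               fit_residual_rms = .residual_rms(a, a0 * shape),
               n_points = nrow(data))
}

#' Reference-method fit selection cascade
#'
#' Chooses the model the reference workflow would use for a TAC:
#' 1. if the first sample is below the second and at least four points are
#'    available, an uptake biexponential is attempted;
#' 2. otherwise (or on failure) a monoexponential is fitted — to all points
#'    if the TAC is monotone decreasing, else to the points from the peak
#'    onward;
#' 3. if fitting fails or the residual RMS exceeds 20% of the peak
#'    activity ("a fit to all data points was not possible"), trapezoidal
#'    integration with a monoexponential tail extrapolation is used.
#'
#' @inheritParams fit_monoexp
#' @return A `tac_fit`; for model `"trapezoid_tail"` the TIA is precomputed
#'   and stored in the fit (see [tia()]).
#' @export
select_fit <- function(data) {
  data <- .check_tac(data)
  if (nrow(data) < 2) .fit_error("need >= 2 points.")
  a <- data$activity_MBq
  peak <- max(a)
  fit <- NULL
  if (nrow(data) >= 4 && a[1] < a[2]) {
    fit <- tryCatch(fit_uptake_biexp(data), rlt_fit_error = function(e) NULL)
  }
  if (is.null(fit)) {
    fit <- tryCatch({
      if (all(diff(a) <= 0)) {
        fit_monoexp(data)
      } else {
        fit_monoexp(data[which.max(a):nrow(data), , drop = FALSE])
      }
    }, rlt_fit_error = function(e) NULL)
  }
  if (is.null(fit) || fit$fit_residual_rms > .RESIDUAL_FRACTION_MAX * peak) {
    tt <- tia_trapezoid_tail(data)
    fit <- tt$fit
  }
  fit
}

#' Evaluate a fitted time-activity curve
#'
#' @param fit A `tac_fit`.
#' @param time_h Times (h) at which to evaluate the fitted model. For a
#'   `trapezoid_tail` fit the tail monoexponential is used (with a
#'   warning), which is only meaningful in the excretion phase.
#' @return Fitted activities in MBq.
#' @export
predict_tac <- function(fit, time_h) {
  stopifnot(inherits(fit, "tac_fit"))
  switch(fit$model,
    monoexp = fit$amplitude_MBq * exp(-fit$clearance_rate_h * time_h),
    uptake_biexp = fit$amplitude_MBq *
      (exp(-fit$clearance_rate_h * time_h) - exp(-fit$uptake_rate_h * time_h)),
    trapezoid_tail = {
      warn("evaluating a trapezoid-tail fit via its tail monoexponential.")
      fit$amplitude_MBq * exp(-fit$clearance_rate_h * time_h)
    },
    abort(sprintf("unknown model '%s'.", fit$model))
  )
}

#' Analytic time-integrated activity
#'
#' Integral of the fitted curve from injection (t = 0) to infinity:
#' \eqn{A_0/\lambda_{eff}} for a monoexponential and
#' \eqn{A_0 (1/\lambda_{eff} - 1/\lambda_{up})} for the uptake
#' biexponential.
#'
#' @param fit A `tac_fit` with model `monoexp` or `uptake_biexp`.
#' @return TIA in MBq h.
#' @examples
#' f <- fit_monoexp(data.frame(time_h = c(24, 72), activity_MBq = c(80, 20)))
#' tia_analytic(f)
#' @export
tia_analytic <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  switch(fit$model,
    monoexp = fit$amplitude_MBq / fit$clearance_rate_h,
    uptake_biexp = fit$amplitude_MBq * (1 / fit$clearance_rate_h - 1 / fit$uptake_rate_h),
    abort("analytic TIA is defined for exponential models only; use tia() or tia_trapezoid_tail().")
  )
}

#' Trapezoidal time-integrated activity with monoexponential tail
#'
#' Integrates a TAC as: a linear rise from zero activity at injection to
#' the first sample, trapezoids between samples, and an analytic tail
#' \eqn{A_{last}/\lambda_{tail}} beyond the last sample, where
#' \eqn{\lambda_{tail}} comes from a monoexponential fit to the last 2 or 3
#' points. By default 3 tail points are used if the last three activities
#' are monotone decreasing (excretion phase reached earlier), else 2.
#'
#' @inheritParams fit_monoexp
#' @param tail_points 2 or 3, or `NULL` for the automatic rule.
#' @return List with `tia_MBqh` and `fit` (a `tac_fit` of model
#'   `"trapezoid_tail"` whose amplitude/clearance describe the tail
#'   monoexponential and whose `tia_MBqh` field stores the integral).
#' @export
tia_trapezoid_tail <- function(data, tail_points = NULL) {
  data <- .check_tac(data)
  n <- nrow(data)
  if (n < 2) .fit_error("trapezoid integration needs >= 2 points.")
  t <- data$time_h
  a <- data$activity_MBq
  if (is.null(tail_points)) {
    tail_points <- if (n >= 3 && all(diff(a[(n - 2):n]) < 0)) 3L else 2L
  }
  tail_points <- as.integer(tail_points)
  stopifnot(tail_points %in% c(2L, 3L))
  tail_points <- min(tail_points, n)
  tail_idx <- (n - tail_points + 1L):n
  if (any(a[tail_idx] <= 0) || any(diff(a[tail_idx]) >= 0)) {
    .fit_error("tail activities must be positive and strictly decreasing.")
  }
  tail_fit <- fit_monoexp(data[tail_idx, , drop = FALSE])
  triangle <- 0.5 * t[1] * a[1]
  traps <- if (n > 1) sum(0.5 * diff(t) * (a[-n] + a[-1])) else 0
  tail_int <- a[n] / tail_fit$clearance_rate_h
  tia <- triangle + traps + tail_int
  fit <- .new_tac_fit("trapezoid_tail", tail_fit$amplitude_MBq,
                      tail_fit$clearance_rate_h,
                      tail_points_used = tail_points,
                      fit_residual_rms = tail_fit$fit_residual_rms,
                      flagged = tail_fit$flagged, n_points = n, tia_MBqh = tia)
  list(tia_MBqh = tia, fit = fit)
}

#' Time-integrated activity of any fit
#'
#' Dispatches to [tia_analytic()] for exponential models; for a
#' `trapezoid_tail` fit returns the integral stored when the fit was
#' produced.
#'
#' @param fit A `tac_fit`.
#' @return TIA in MBq h.
#' @export
tia <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  if (fit$model == "trapezoid_tail") fit$tia_MBqh else tia_analytic(fit)
}

#' @export
tidy.tac_fit <- function(x, ...) {
  tibble(
    term = c("amplitude_MBq", "clearance_rate_h", "uptake_rate_h"),
    estimate = c(x$amplitude_MBq, x$clearance_rate_h, x$uptake_rate_h)
  ) |> dplyr::filter(is.finite(.data$estimate))
}

#' @export
glance.tac_fit <- function(x, ...) {
  tibble(
    model = x$model, amplitude_MBq = x$amplitude_MBq,
    clearance_rate_h = x$clearance_rate_h, uptake_rate_h = x$uptake_rate_h,
    t_eff_h = x$t_eff_h, tia_MBqh = tia(x),
    fit_residual_rms = x$fit_residual_rms, n_points = x$n_points,
    flagged = x$flagged
  )
}
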