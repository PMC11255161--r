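# Fixtures built in code: exact kinetic curves, small cohort configs, and
# numeric-quadrature oracles independent of the analytic TIA formulas.

monoexp_tac <- function(a0, t_eff_h, times_h) {
  tibble::tibble(time_h = times_h,
                 activity_MBq = a0 * exp(-log(2) / t_eff_h * times_h))
}

biexp_tac <- function(a0, t_eff_h, t_up_h, times_h) {
  le <- log(2) / t_eff_h
  lu <- log(2) / t_up_h
  tibble::tibble(time_h = times_h,
                 activity_MBq = a0 * (exp(-le * times_h) - exp(-lu * times_h)))
}

# adaptive-quadrature TIA of a true_kinetics-like list (oracle)
quad_tia <- function(kin, upper = Inf) {
  f <- function(t) {
    if (kin$model == "monoexp") {
      kin$amplitude_MBq * exp(-kin$clearance_rate_h * t)
    } else {
      kin$amplitude_MBq * (exp(-kin$clearance_rate_h * t) - exp(-kin$uptake_rate_h * t))
    }
  }
  stats::integrate(f, 0, upper, rel.tol = 1e-10)$value
}

# quadrature of the piecewise trapezoid-tail model: linear to the first
# point, linear between points, exponential tail from the last point
quad_trapezoid_tail <- function(times, acts, lambda_tail) {
  f <- function(t) {
    sapply(t, function(ti) {
      if (ti <= times[1]) return(acts[1] * ti / times[1])
      if (ti <= times[length(times)]) {
        return(stats::approx(times, acts, xout = ti)$y)
      }
      acts[length(acts)] * exp(-lambda_tail * (ti - times[length(times)]))
    })
  }
  stats::integrate(f, 0, 2000, rel.tol = 1e-9, subdivisions = 2000L)$value
}

# small cohort for fast end-to-end tests
small_config <- function(...) {
  cohort_config(n_patients = 3, lesion_counts = c(bone = 4, node = 2),
                lesion_cycle_counts = c(6, 6, 5, 4), seed = 11, ...)
}

# kinetics tables with cycle-constant targets (no systematic cycle trend)
constant_organ_kinetics <- function() {
  k <- default_organ_kinetics()
  k |>
    dplyr::group_by(kind) |>
    dplyr::mutate(dplyr::across(c(norm_dose_mean, norm_dose_sd,
                                  t_eff_mean, t_eff_sd), dplyr::first)) |>
    dplyr::ungroup()
}

constant_lesion_kinetics <- function() {
  k <- default_lesion_kinetics()
  k |>
    dplyr::group_by(kind) |>
    dplyr::mutate(dplyr::across(c(norm_dose_mean, norm_dose_sd,
                                  t_eff_mean, t_eff_sd), dplyr::first)) |>
    dplyr::ungroup()
}
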