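test_that("monoexponential fit recovers exact curves and two-point algebra", {
  tac <- monoexp_tac(100, 50, c(2, 24, 48, 120))
  f <- fit_monoexp(tac)
  expect_equal(f$amplitude_MBq, 100, tolerance = 1e-6)
  expect_equal(f$t_eff_h, 50, tolerance = 1e-6)
  expect_false(f$flagged)
  # two points: lambda = ln4 / 48, T_eff = 24 h, A0 = 160 MBq
  f2 <- fit_monoexp(data.frame(time_h = c(24, 72), activity_MBq = c(80, 20)))
  expect_equal(f2$clearance_rate_h, log(4) / 48, tolerance = 1e-12)
  expect_equal(f2$t_eff_h, 24)
  expect_equal(f2$amplitude_MBq, 160, tolerance = 1e-9)
})

test_that("degenerate monoexponential inputs are flagged or rejected", {
  const <- data.frame(time_h = c(2, 24, 48, 120), activity_MBq = rep(50, 4))
  f <- fit_monoexp(const)
  expect_true(f$flagged) # lambda pinned at the lower (slow) bound
  expect_error(fit_monoexp(data.frame(time_h = c(2, 24), activity_MBq = c(5, 0))),
               "positive", class = "rlt_fit_error")
})

test_that("uptake biexponential fit recovers exact curves and rejects bad shapes", {
  tac <- biexp_tac(120, 60, 1.5, c(2, 24, 48, 120))
  f <- fit_uptake_biexp(tac)
  expect_equal(f$amplitude_MBq, 120, tolerance = 1e-5)
  expect_equal(log(2) / f$clearance_rate_h, 60, tolerance = 1e-5)
  expect_equal(log(2) / f$uptake_rate_h, 1.5, tolerance = 1e-4)
  # residual definition: fitted curve reproduces inputs within residual RMS
  resid <- tac$activity_MBq - predict_tac(f, tac$time_h)
  expect_equal(sqrt(mean(resid^2)), f$fit_residual_rms, tolerance = 1e-8)
  # peak at first sample -> error, caller falls back to monoexp
  expect_error(fit_uptake_biexp(monoexp_tac(100, 50, c(2, 24, 48, 120))),
               "peak", class = "rlt_fit_error")
  expect_error(fit_uptake_biexp(tac[1:3, ]), ">= 4", class = "rlt_fit_error")
})

test_that("fit selection cascade picks monoexp, biexp, or trapezoid fallback", {
  expect_equal(select_fit(monoexp_tac(100, 40, c(2, 24, 48, 96)))$model, "monoexp")
  peaked <- biexp_tac(120, 60, 8, c(2, 24, 48, 120)) # peak ~ 26 h
  expect_equal(select_fit(peaked)$model, "uptake_biexp")
  # pathological TAC: no exponential gets residual under 20% of peak
  ugly <- data.frame(time_h = c(2, 24, 48, 120), activity_MBq = c(100, 5, 80, 40))
  sel <- select_fit(ugly)
  expect_equal(sel$model, "trapezoid_tail")
  expect_true(is.finite(tia(sel)))
})

test_that("fit output is invariant to sample order", {
  tac <- monoexp_tac(80, 35, c(2, 24, 48, 120))
  tac$activity_MBq <- tac$activity_MBq * c(1.03, 0.98, 1.01, 0.99)
  shuffled <- tac[c(3, 1, 4, 2), ]
  expect_equal(glance(fit_monoexp(tac)), glance(fit_monoexp(shuffled)))
})

test_that("analytic TIA matches closed form, limits and quadrature", {
  f <- fit_monoexp(monoexp_tac(100, log(2) / 0.01, c(10, 100, 200)))
  expect_equal(tia_analytic(f), 10000, tolerance = 1e-6)
  f50 <- fit_monoexp(monoexp_tac(100, 50, c(2, 24, 48, 120)))
  expect_equal(tia_analytic(f50), 100 * 50 / log(2), tolerance = 1e-6)
  expect_equal(tia_analytic(f50),
               quad_tia(list(model = "monoexp", amplitude_MBq = 100,
                             clearance_rate_h = log(2) / 50)),
               tolerance = 1e-4)
  # biexp -> monoexp limit as the uptake rate grows (sample before the peak)
  fb <- fit_uptake_biexp(biexp_tac(100, 50, 0.05, c(0.01, 24, 48, 120)))
  expect_equal(tia_analytic(fb), 100 * 50 / log(2), tolerance = 2e-3)
  expect_error(tia_analytic(select_fit(
    data.frame(time_h = c(2, 24, 48, 120), activity_MBq = c(100, 5, 80, 40)))),
    "exponential")
})

test_that("trapezoid-with-tail integration matches hand geometry and quadrature", {
  two <- data.frame(time_h = c(24, 72), activity_MBq = c(80, 20))
  # trapezoid panel between the samples alone: (80+20)/2 * 48 = 2400
  expect_equal(0.5 * (80 + 20) * 48, 2400)
  tt <- tia_trapezoid_tail(two)
  # triangle 960 + trapezoid 2400 + tail 20/(ln4/48) = 4052.49
  expect_equal(tt$tia_MBqh, 960 + 2400 + 20 / (log(4) / 48), tolerance = 1e-9)
  expect_equal(tt$tia_MBqh, 4052.49, tolerance = 1e-4)
  expect_equal(tt$tia_MBqh,
               quad_trapezoid_tail(two$time_h, two$activity_MBq,
                                   tt$fit$clearance_rate_h),
               tolerance = 1e-4)
  expect_equal(tt$fit$tail_points_used, 2L)
  # three decreasing tail points -> 3 used
  three <- monoexp_tac(100, 40, c(2, 24, 48, 120))
  expect_equal(tia_trapezoid_tail(three)$fit$tail_points_used, 3L)
  # densely sampled monoexponential: trapezoid result -> analytic within 2%
  dense <- monoexp_tac(100, 50, seq(1, 300, by = 2))
  expect_equal(tia_trapezoid_tail(dense)$tia_MBqh, 100 * 50 / log(2),
               tolerance = 0.02)
  expect_error(tia_trapezoid_tail(
    data.frame(time_h = c(2, 24, 48), activity_MBq = c(50, 10, 20))),
    "decreasing", class = "rlt_fit_error")
})

test_that("TIA is monotone in half-life and amplitude and matches quadrature broadly", {
  withr::local_seed(101)
  teffs <- sort(runif(8, 10, 120))
  tias <- vapply(teffs, function(te) {
    tia_analytic(fit_monoexp(monoexp_tac(100, te, c(2, 24, 48, 120))))
  }, numeric(1))
  expect_true(all(diff(tias) > 0))
  a0s <- sort(runif(8, 10, 500))
  tias_a <- vapply(a0s, function(a) {
    tia_analytic(fit_monoexp(monoexp_tac(a, 50, c(2, 24, 48, 120))))
  }, numeric(1))
  expect_true(all(diff(tias_a) > 0))
  # random kinetics: analytic vs adaptive quadrature
  for (i in 1:200) {
    kin <- list(model = sample(c("monoexp", "uptake_biexp"), 1),
                amplitude_MBq = runif(1, 1, 1000),
                clearance_rate_h = log(2) / runif(1, 5, 200),
                uptake_rate_h = log(2) / runif(1, 0.2, 4))
    analytic <- if (kin$model == "monoexp") {
      kin$amplitude_MBq / kin$clearance_rate_h
    } else {
      kin$amplitude_MBq * (1 / kin$clearance_rate_h - 1 / kin$uptake_rate_h)
    }
    expect_equal(analytic, quad_tia(kin), tolerance = 1e-6)
  }
})
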