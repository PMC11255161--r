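test_that("SM1 rescaling is exact when the single point sits on the cycle-1 curve", {
  reg <- source_region("K", "kidney", mass_g = 300)
  tac1 <- monoexp_tac(150, 40, c(2, 24, 48, 120))
  fit1 <- select_fit(tac1)
  d1 <- tia(fit1) * self_dose_factor(reg)
  for (t in c(2, 24, 48, 120)) {
    obs <- list(t_single_h = t, measured_MBq = predict_tac(fit1, t),
                injected_MBq = 6200)
    out <- sm1_dose(fit1, obs, reg)
    expect_equal(out$dose_mGy, d1, tolerance = 1e-9)
    expect_equal(out$t_eff_h, fit1$t_eff_h)
  }
  # linear in the measured activity
  half <- sm1_dose(fit1, list(t_single_h = 48,
                              measured_MBq = 0.5 * predict_tac(fit1, 48),
                              injected_MBq = 6200), reg)
  expect_equal(half$dose_mGy, 0.5 * d1, tolerance = 1e-9)
  expect_error(sm1_dose(fit1, list(t_single_h = 500, measured_MBq = 1,
                                   injected_MBq = 6200), reg), "400")
})

test_that("SM1 error under changed kinetics matches the curve-integral oracle", {
  reg <- source_region("K", "kidney", mass_g = 250)
  kin1 <- list(model = "monoexp", amplitude_MBq = 150, clearance_rate_h = log(2) / 40)
  kin2 <- list(model = "monoexp", amplitude_MBq = 130, clearance_rate_h = log(2) / 55)
  fit1 <- select_fit(monoexp_tac(150, 40, c(2, 24, 48, 120)))
  t_obs <- 48
  a2 <- kin2$amplitude_MBq * exp(-kin2$clearance_rate_h * t_obs)
  out <- sm1_dose(fit1, list(t_single_h = t_obs, measured_MBq = a2,
                             injected_MBq = 6000), reg)
  true_dose2 <- quad_tia(kin2) * self_dose_factor(reg)
  # brute-force oracle: SM1 integrates the cycle-1 curve rescaled at t_obs
  oracle_ratio <- (a2 / (kin1$amplitude_MBq * exp(-kin1$clearance_rate_h * t_obs))) *
    quad_tia(kin1) / quad_tia(kin2)
  expect_equal(out$dose_mGy / true_dose2, oracle_ratio, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(out$dose_mGy, true_dose2)))
})

test_that("SM2 and SM3 follow their display equations exactly", {
  expect_equal(sm2_dose(4000, 6200, 6200), 4000)
  expect_equal(sm2_dose(4000, 6200, 5000), 3225.8, tolerance = 1e-4)
  expect_equal(sm2_dose(4000, 6200, 0), 0)
  expect_error(sm2_dose(4000, 0, 5000), "positive")
  expect_equal(sm3_dose(3600, 6000, 4800, 6000, 6000), 4200)
  expect_error(sm3_dose(1, 1, 1, -1, 1), "positive")
  # SM3 degenerates to SM2 when the two normalized doses agree,
  # and is the mean of the two one-cycle extrapolations in general
  withr::local_seed(14)
  for (i in 1:20) {
    d1 <- runif(1, 1000, 8000); a1 <- runif(1, 5000, 6700)
    d2 <- runif(1, 1000, 8000); a2 <- runif(1, 5000, 6700)
    ai <- runif(1, 5000, 6700)
    expect_equal(sm3_dose(d1, a1, d2, a2, ai),
                 (sm2_dose(d1, a1, ai) + sm2_dose(d2, a2, ai)) / 2)
  }
  expect_equal(sm3_dose(4000, 6200, 4000 * 5 / 6.2, 5000, 5500),
               sm2_dose(4000, 6200, 5500))
})

test_that("simplified runs reproduce the reference when its assumptions hold", {
  cfg <- small_config(noise_cv = 0, intercycle_cv = 0,
                      organ_kinetics = constant_organ_kinetics(),
                      lesion_kinetics = constant_lesion_kinetics())
  coh <- generate_cohort(cfg)
  rm_rec <- run_reference_dosimetry(coh)
  for (tp in c("2-4h", "24h", "48h", "72-168h")) {
    sm1 <- run_simplified(coh, rm_rec, method = "SM1", tp = tp)
    pairs <- comparison_pairs(sm1, rm_rec, cycles = 2:4)
    expect_equal(pairs$d_SM, pairs$d_RM, tolerance = 1e-6)
  }
})

test_that("SM2 totals with equal activities are four times the first cycle", {
  cfg <- small_config(noise_cv = 0, activity_sd_GBq = 0)
  coh <- generate_cohort(cfg)
  rm_rec <- run_reference_dosimetry(coh)
  sm2 <- run_simplified(coh, rm_rec, method = "SM2")
  tot <- cumulate_doses(sm2, 4)
  c1 <- rm_rec |> dplyr::filter(cycle == 1, kind %in% c("kidney", "parotid", "submandibular"))
  expect_equal(
    tot |> dplyr::arrange(region_id) |> dplyr::pull(total_Gy),
    c1 |> dplyr::arrange(region_id) |> dplyr::pull(dose_mGy) * 4 / 1000,
    tolerance = 1e-10
  )
})

test_that("SM bookkeeping: record counts and lesion refusal", {
  coh <- generate_cohort(cohort_config(seed = 5))
  rm_rec <- run_reference_dosimetry(coh)
  sm1 <- run_simplified(coh, rm_rec, method = "SM1", tp = "48h",
                        kinds = "kidney")
  expect_equal(nrow(sm1 |> dplyr::filter(cycle > 1)), 16 * 3)
  expect_error(run_simplified(coh, rm_rec, method = "SM2",
                              kinds = c("kidney", "lesion_bone")),
               "lesion", class = "rlt_method_error")
  sm3 <- run_simplified(coh, rm_rec, method = "SM3")
  # cycles 1-2 copied from the reference method
  copied <- comparison_pairs(sm3 |> dplyr::filter(cycle <= 2), rm_rec)
  expect_equal(copied$d_SM, copied$d_RM)
})
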