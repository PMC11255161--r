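test_that("target inversion closes the loop on forward dosimetry", {
  reg <- source_region("L", "lesion_soft", mass_g = 1)
  kin <- kinetics_from_targets(1.0, 50, 6200, reg)
  # TIA = requested dose * injected / S(m) = 6200 / 85.31 = 72.68 MBq.h
  tia_kin <- kin$amplitude_MBq / kin$clearance_rate_h
  expect_equal(tia_kin, 6200 / self_dose_factor(reg), tolerance = 1e-12)
  expect_equal(tia_kin, 72.68, tolerance = 1e-3)
  expect_equal(kin$amplitude_MBq, tia_kin * log(2) / 50, tolerance = 1e-12)
  # forward normalized dose returns the request to 1e-9 relative,
  # cross-checked through numeric quadrature of the returned curve
  fwd <- quad_tia(kin) * self_dose_factor(reg) / 6200
  expect_equal(fwd, 1.0, tolerance = 1e-6)
  # linearity: doubling the requested dose doubles amplitude only
  kin2 <- kinetics_from_targets(2.0, 50, 6200, reg)
  expect_equal(kin2$amplitude_MBq, 2 * kin$amplitude_MBq)
  expect_equal(kin2$clearance_rate_h, kin$clearance_rate_h)
})

test_that("uptake-biexponential inversion accounts for the uptake deficit", {
  reg <- source_region("L", "lesion_soft", mass_g = 2)
  kin <- kinetics_from_targets(3.0, 55, 6000, reg, model = "uptake_biexp",
                               uptake_half_life_h = 1)
  fwd <- quad_tia(kin) * self_dose_factor(reg) / 6000
  expect_equal(fwd, 3.0, tolerance = 1e-6)
  expect_gt(kin$uptake_rate_h, kin$clearance_rate_h)
  expect_error(kinetics_from_targets(3.0, 55, 6000, reg, model = "uptake_biexp",
                                     uptake_half_life_h = 80), "exceed")
  expect_error(kinetics_from_targets(-1, 55, 6000, reg), "positive")
})

test_that("simulated TACs are exact without noise and reproducible with it", {
  kin <- list(model = "monoexp", amplitude_MBq = 100,
              clearance_rate_h = log(2) / 50, uptake_rate_h = NA_real_)
  tac <- simulate_tac(kin, c(0, 50), noise_cv = 0)
  expect_equal(tac$activity_MBq, c(100, 50))
  a <- simulate_tac(kin, c(2, 24, 48, 120), noise_cv = 0.1, seed = 5)
  b <- simulate_tac(kin, c(2, 24, 48, 120), noise_cv = 0.1, seed = 5)
  expect_identical(a, b)
  # mean-one multiplicative noise
  withr::local_seed(9)
  many <- replicate(4000, simulate_tac(kin, 24, noise_cv = 0.05)$activity_MBq)
  expect_equal(mean(many), 100 * exp(-log(2) / 50 * 24), tolerance = 0.01)
  expect_error(simulate_tac(kin, c(2, 24), noise_cv = -0.1), "non-negative")
})

test_that("default cohort reproduces the study composition", {
  coh <- generate_cohort(cohort_config(seed = 21))
  expect_equal(coh$config$n_patients, 16L)
  expect_equal(coh$config$n_cycles, 4L)
  les <- coh$regions[grepl("^lesion", coh$regions$kind), ]
  expect_equal(nrow(les), 90)
  expect_equal(unname(table(les$lesion_type)[c("bone", "node", "local")]),
               c(70L, 19L, 1L), ignore_attr = TRUE)
  expect_true(all(table(les$patient_id) <= 10))
  # injected activities within the protocol range, in MBq
  expect_true(all(coh$cycles$injected_MBq >= 5000 & coh$cycles$injected_MBq <= 6700))
  # per-cycle lesion counts follow the dropout plan and never increase
  counts <- coh$truth |>
    dplyr::filter(grepl("^lesion", kind)) |>
    dplyr::count(cycle) |>
    dplyr::pull(n)
  expect_equal(counts, c(90L, 87L, 79L, 67L))
  expect_true(all(diff(counts) <= 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_config(seed = 33))
  b <- generate_cohort(cohort_config(seed = 33))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)
  c_ <- generate_cohort(cohort_config(seed = 34))
  expect_false(identical(a$measurements, c_$measurements))
})

test_that("degenerate variability collapses cycles to identical kinetics", {
  cfg <- cohort_config(
    n_patients = 3, lesion_counts = c(bone = 2),
    lesion_cycle_counts = c(2, 2, 2, 2),
    organ_kinetics = constant_organ_kinetics(),
    lesion_kinetics = constant_lesion_kinetics(),
    intercycle_cv = 0, noise_cv = 0, seed = 4
  )
  coh <- generate_cohort(cfg)
  per_region <- coh$truth |>
    dplyr::group_by(region_id) |>
    dplyr::summarise(n_dose = dplyr::n_distinct(round(true_norm_dose, 12)),
                     n_teff = dplyr::n_distinct(round(true_t_eff_h, 12)))
  expect_true(all(per_region$n_dose == 1))
  expect_true(all(per_region$n_teff == 1))
})

test_that("infeasible lesion plans are rejected", {
  expect_error(cohort_config(n_patients = 2, lesion_counts = c(bone = 30)),
               "infeasible", class = "rlt_config_error")
  expect_error(cohort_config(lesion_cycle_counts = c(90, 91, 79, 67)),
               "non-increasing", class = "rlt_config_error")
})

test_that("last time point distribution has the protocol mean", {
  cfg <- cohort_config(seed = 1)
  withr::local_seed(77)
  draws <- sample(cfg$last_tp_choices_h, 1e4, replace = TRUE,
                  prob = cfg$last_tp_weights)
  expect_lt(abs(mean(draws) - 130), 2)
  expect_true(all(draws %in% c(72, 96, 120, 144, 168)))
  # generated cohorts draw from the same support
  coh <- generate_cohort(cfg)
  expect_true(all(coh$cycles$last_tp_h %in% cfg$last_tp_choices_h))
})
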