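# Virtual-patient exposure, threshold classification, adherence gating.

test_that("a variability-free day-28 population all reach the typical Cmax", {
  spec <- simulation_spec(
    occasion_models = list(degenerate_model(al_population_model("table3_day28"))),
    n_patients = 50, seed = 1)
  cm <- simulate_exposure(spec, regimen(2000))
  # 90-dose accumulation adds < 0.1% to the frozen single-dose value
  expect_true(all(abs(cm / 49.66364 - 1) < 0.001))
})

test_that("extending 90 days to a year leaves each patient's Cmax unchanged", {
  spec <- simulation_spec(n_patients = 300, seed = 5)
  cm90 <- simulate_exposure(spec, regimen(2000, duration_days = 90))
  cm365 <- simulate_exposure(spec, regimen(2000, duration_days = 365))
  expect_lt(max(abs(cm365 / cm90 - 1)), 0.001)
})

test_that("exposure uses common random numbers across doses and is monotone", {
  spec <- simulation_spec(n_patients = 500, seed = 7)
  cm1 <- simulate_exposure(spec, regimen(1000))
  cm2 <- simulate_exposure(spec, regimen(2000))
  expect_equal(unclass(cm2)[, ], unclass(2 * cm1)[, ], tolerance = 1e-9)
  expect_true(all(cm2 >= cm1))
})

test_that("classification respects trivial cut-offs and the cut-off ordering", {
  spec <- simulation_spec(n_patients = 400, seed = 3)
  cm <- simulate_exposure(spec, regimen(1500))
  all_in <- classify(cm, efficacy_criteria(1e-9, 1e-10))
  expect_true(all(all_in$progression_inhibited))
  none <- classify(cm, efficacy_criteria(1e9, 1e8))
  expect_false(any(none$progression_inhibited) || any(none$death_prevented))
  fl <- classify(cm, efficacy_criteria())
  expect_true(all(fl$death_prevented[fl$progression_inhibited]))
  expect_error(efficacy_criteria(10, 20), ">= death")
})

test_that("single-occasion mode uses only the designated occasion", {
  spec <- simulation_spec(criterion_mode = "single_occasion",
                          n_patients = 300, seed = 9)
  cm <- simulate_exposure(spec, regimen(2000))
  fl <- classify(cm, efficacy_criteria())
  direct <- cm[, 3] >= 32.39
  expect_identical(fl$progression_inhibited, unname(direct))
})

test_that("patient-level gating is the identity at p=1 and annihilates at p=0", {
  spec <- simulation_spec(n_patients = 300, seed = 2)
  fl <- classify(simulate_exposure(spec, regimen(2500)), efficacy_criteria())
  same <- apply_adherence(fl, adherence_scenario(1), seed = 1)
  expect_identical(same$progression_inhibited, fl$progression_inhibited)
  none <- apply_adherence(fl, adherence_scenario(0), seed = 1)
  expect_false(any(none$progression_inhibited) || any(none$death_prevented))
})

test_that("patient-level gating thins responders multiplicatively", {
  n <- 1e5
  flags <- tibble::tibble(progression_inhibited = rep(TRUE, n),
                          death_prevented = rep(TRUE, n))
  p <- 0.6
  gated <- apply_adherence(flags, adherence_scenario(p), seed = 8)
  frac <- mean(gated$progression_inhibited)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("dose-level gating re-simulates exposure and is gentler than patient-level", {
  spec <- simulation_spec(
    occasion_models = list(al_population_model("table3_day28")),
    criterion_mode = "single_occasion", n_patients = 150, seed = 4)
  fl <- classify(simulate_exposure(spec, regimen(2000)), efficacy_criteria())
  dose_gated <- apply_adherence(fl, adherence_scenario(0.5, "dose_level"),
                                seed = 5)
  pat_gated <- apply_adherence(fl, adherence_scenario(0.5, "patient_level"),
                               seed = 5)
  # with a short half-life, skipping half the doses barely changes the
  # single-dose Cmax, so dose-level gating removes far fewer responders
  expect_gt(mean(dose_gated$death_prevented), mean(pat_gated$death_prevented))
  ident <- apply_adherence(fl, adherence_scenario(1, "dose_level"), seed = 6)
  expect_identical(ident$death_prevented, fl$death_prevented)
})

test_that("mortality never exceeds progression across the regimen grid", {
  spec <- simulation_spec(n_patients = 500, seed = 6)
  eff <- simulate_efficacy(spec, doses_mg = c(1000, 2000, 3000),
                           adherence = c(1, 0.5), n_replicates = 5)
  expect_true(all(eff$mortality_pct <= eff$progression_pct + 1e-9))
  expect_true(all(eff$progression_lo <= eff$progression_pct &
                    eff$progression_pct <= eff$progression_hi))
})

test_that("analytic and Monte-Carlo adherence gating agree", {
  res <- adherence_gated_efficacy(55, p = 0.5, n = 1000, n_replicates = 300,
                                  seed = 2)
  expect_equal(res$analytic_pct, 77.5)
  expect_lt(abs(res$mean_pct - res$analytic_pct), 3 * res$sd_pct / sqrt(300))
})

test_that("invalid simulation sizes are rejected", {
  expect_error(simulation_spec(n_patients = 0), ">= 1")
  expect_error(regimen(0), "daily_dose_mg > 0")
  expect_error(adherence_scenario(1.2))
})
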