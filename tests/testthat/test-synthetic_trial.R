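# Trial generator and the tabular event format.

default_models <- function() {
  m <- al_model_presets()
  list(day1 = m$table1_day1, day14 = m$table2_day14, day28 = m$table3_day28)
}

test_that("the default design yields 31 PK subjects with 12 observations per occasion", {
  d <- generate_trial(trial_design(), default_models(), seed = 1)
  expect_identical(length(unique(d$ID)), 31L)  # 15 + 16 (controls have no PK)
  occ <- unique(d[, c("ID", "OCC")])
  expect_identical(nrow(occ), 47L)  # 15 day-1 + 16 day-14 + 16 day-28
  counts <- table(d$EVID[d$EVID == 0], paste(d$ID, d$OCC)[d$EVID == 0])
  expect_true(all(counts == 12))
  # titration arm: day 14 is the last 1,000-mg day, day 28 the last
  # 1,500-mg day (1,500 starts on day 15, 2,000 on day 29)
  expect_true(all(d$AMT[d$EVID == 1 & d$OCC == 14] == 1000))
  expect_true(all(d$AMT[d$EVID == 1 & d$OCC == 28] == 1500))
})

test_that("zero-variability, zero-error data equal the typical profiles", {
  mods <- list(day1 = degenerate_model())
  d <- generate_trial(recovery_design(n = 4), mods, seed = 3)
  p <- structural_params(0.85, 42.82, 20.9)
  expected <- concentration(p, dose_schedule(0, 1000),
                            trial_design()$sampling_times)
  for (id in unique(d$ID)) {
    expect_equal(d$DV[d$ID == id & d$EVID == 0], expected, tolerance = 1e-12)
  }
})

test_that("pre-dose observations are floored residual noise with a flag", {
  d <- generate_trial(recovery_design(n = 200),
                      list(day1 = al_population_model("table1_day1")), seed = 6)
  t0 <- d[d$EVID == 0 & d$TIME == 0, ]
  expect_true(all(t0$DV >= 0))
  expect_true(all(t0$DV[t0$FLOOR == 1] == 0))
  expect_gt(mean(t0$FLOOR), 0.3)  # about half the zero-time draws go negative
})

test_that("generation is deterministic and files round-trip losslessly", {
  d1 <- generate_trial(trial_design(), default_models(), seed = 5)
  d2 <- generate_trial(trial_design(), default_models(), seed = 5)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d1, f1); write_dataset(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_dataset(f1)
  ref <- d1[, names(back)]
  attr(ref, "true_params") <- NULL  # simulation truth is not file content
  expect_equal(as.data.frame(back), as.data.frame(ref), tolerance = 1e-12)
})

test_that("a missing occasion model is an explicit error", {
  expect_error(
    generate_trial(trial_design(), list(day1 = al_population_model("table1_day1")),
                   seed = 1),
    "day14")
})

test_that("the reader rejects malformed files with line-numbered messages", {
  d <- generate_trial(recovery_design(n = 2),
                      list(day1 = al_population_model("table1_day1")), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- d; bad$DV[6] <- -1
  write_dataset(bad, path)
  expect_error(read_dataset(path), "negative concentration \\(line 7\\)")

  bad <- d; bad$DV[1] <- 5  # dose row with a DV
  write_dataset(bad, path)
  expect_error(read_dataset(path), "ambiguity \\(line 2\\)")

  bad <- d[d$EVID == 0, ]  # no dose rows
  write_dataset(bad, path)
  expect_error(read_dataset(path), "no dose row")

  write_dataset(d, path)
  extra <- readLines(path)
  extra[1] <- paste0(extra[1], ",BOGUS")
  extra[-1] <- paste0(extra[-1], ",1")
  writeLines(extra, path)
  expect_error(read_dataset(path), "unknown dataset columns: BOGUS")
})

test_that("positive concentrations before the first dose raise a warning", {
  d <- generate_trial(recovery_design(n = 2),
                      list(day1 = al_population_model("table1_day1")), seed = 2)
  # move the dose of subject 1 to 0.5 h so the 0- and 0.25-h samples precede it
  path <- withr::local_tempfile(fileext = ".csv")
  d$TIME[d$ID == 1 & d$EVID == 1] <- 0.5
  d$DV[d$ID == 1 & d$EVID == 0 & d$TIME == 0.25] <- 1.0
  write_dataset(d, path)
  expect_warning(read_dataset(path), "pre-dose observation")
})

test_that("generated Cmax distribution matches the population model (KS)", {
  n <- 2000
  pop <- al_population_model("table1_day1")
  d <- generate_trial(recovery_design(n = n), list(day1 = pop), seed = 10)
  tp <- attr(d, "true_params")
  cmax_of <- function(tk0, v, cl) {
    ke <- cl / v
    (1000 / (tk0 * cl)) * (1 - exp(-ke * tk0))
  }
  sim <- cmax_of(tp$tk0, tp$v, tp$cl)
  pat <- sample_patients(pop, n, seed = 11)
  ref <- cmax_of(pat$tk0, pat$v, pat$cl)
  ks <- suppressWarnings(stats::ks.test(sim, ref))
  expect_gt(ks$p.value, 0.01)
})
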