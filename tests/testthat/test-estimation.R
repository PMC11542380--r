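# SAEM estimation, likelihood, information criteria, screening, diagnostics.

test_that("information criteria match hand-computed values exactly", {
  ic <- information_criteria(100, 8, 16, 192)
  expect_equal(ic$AIC, 116, tolerance = 1e-9)
  expect_equal(ic$BIC, 100 + 8 * log(16), tolerance = 1e-9)
  expect_equal(ic$BICc, 100 + 6 * log(16) + 2 * log(192), tolerance = 1e-9)
  ic0 <- information_criteria(57.5, 0, 10, 120)
  expect_identical(c(ic0$AIC, ic0$BIC, ic0$BICc), c(57.5, 57.5, 57.5))
  # BIC >= AIC once ln(N) >= 2
  ic8 <- information_criteria(0, 5, 8, 80)
  expect_gte(ic8$BIC, ic8$AIC)
})

test_that("noise-free, variability-free data recover the typicals nearly exactly", {
  d <- generate_trial(recovery_design(n = 4),
                      list(day1 = degenerate_model()), seed = 3)
  fit <- suppressWarnings(
    saem_fit(occasion_data(d, 1),
             settings = saem_settings(n_burn = 200, n_smooth = 200, seed = 2)))
  expect_lt(abs(fit$model$tk0$typical / 0.85 - 1), 0.001)
  expect_lt(abs(fit$model$v$typical / 42.82 - 1), 0.001)
  expect_lt(abs(fit$model$cl$typical / 20.9 - 1), 0.001)
  # omegas collapse to negligible spread (< 1% CV; v's omega is on the
  # natural scale of a ~43 L parameter)
  expect_true(all(fit$omega / c(1, 42.82, 1) < 0.01))
})

test_that("fits are deterministic given the seed", {
  d <- table1_dataset(seed = 42)
  f1 <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                  settings = quick_settings(seed = 9)))
  f2 <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                  settings = quick_settings(seed = 9)))
  expect_identical(f1$mu_phi, f2$mu_phi)
  expect_identical(f1$omega, f2$omega)
  expect_identical(c(f1$err_a, f1$err_b), c(f2$err_a, f2$err_b))
})

test_that("changing the fit seed moves estimates far less than the signal", {
  d <- table1_dataset(seed = 42)
  f1 <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                  settings = saem_settings(seed = 9)))
  f2 <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                  settings = saem_settings(seed = 18)))
  t1 <- c(f1$model$tk0$typical, f1$model$v$typical, f1$model$cl$typical)
  t2 <- c(f2$model$tk0$typical, f2$model$v$typical, f2$model$cl$typical)
  # replicate-fit dispersion: Monte-Carlo noise under 10% per parameter
  expect_true(all(abs(t2 / t1 - 1) < 0.10))
})

test_that("the SAEM trajectory improves the objective from its initial values", {
  d <- table1_dataset(seed = 7)
  fit <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                   settings = quick_settings(seed = 3)))
  tr <- fit$trajectory
  # the fit should have moved the error model towards the truth (a=0.36,b=0.32)
  expect_lt(abs(tr$b[nrow(tr)] - 0.32), abs(tr$b[1] - 0.32) + 0.05)
  expect_true(fit$converged || max(abs(diff(tail(tr$cl, 20)))) < 1)
})

test_that("the OFV approaches the closed form in the omega -> 0 limit", {
  d <- generate_trial(recovery_design(n = 6),
                      list(day1 = degenerate_model()), seed = 5)
  pop <- population_model(
    tk0 = param_dist(0.85, 1e-6, "lognormal"),
    v = param_dist(42.82, 1e-6, "normal"),
    cl = param_dist(20.9, 1e-6, "lognormal"),
    err_a = 0.5, err_b = 0.1, label = "limit")
  fit <- truth_fit(d, pop)
  obs <- d[d$EVID == 0, ]
  p <- structural_params(0.85, 42.82, 20.9)
  f <- concentration(p, dose_schedule(0, 1000), obs$TIME[obs$ID == 1])
  f <- rep(f, times = 6)
  g <- 0.5 + 0.1 * f
  closed <- sum(log(2 * pi * g^2) + ((obs$DV - f) / g)^2)
  ll <- loglikelihood(fit, d, mc_size = 2000, seed = 1)
  expect_equal(ll$ofv, closed, tolerance = 1e-4)
})

test_that("the OFV is better for the generating model than a mis-specified one", {
  d <- table1_dataset(seed = 12)
  pop <- al_population_model("table1_day1")
  fit_true <- truth_fit(d, pop)
  bad_pop <- population_model(
    tk0 = pop$tk0, v = pop$v,
    cl = param_dist(pop$cl$typical * 2, pop$cl$omega, "lognormal"),
    err_a = pop$err_a, err_b = pop$err_b, label = "bad")
  fit_bad <- truth_fit(d, bad_pop)
  fit_bad$phi_modes <- fit_true$phi_modes  # same starting modes; IS re-centres
  ofv_true <- loglikelihood(fit_true, d, mc_size = 2000, seed = 2)$ofv
  ofv_bad <- loglikelihood(fit_bad, d, mc_size = 2000, seed = 2)$ofv
  expect_lt(ofv_true, ofv_bad)
})

test_that("OFV Monte-Carlo error is small and small mc sizes are rejected", {
  d <- table1_dataset(seed = 42)
  fit <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                   settings = quick_settings(seed = 9)))
  expect_error(loglikelihood(fit, d, mc_size = 99), "at least 100")
  ll <- loglikelihood(fit, d, mc_size = 10000, seed = 3)
  expect_lt(ll$mc_se, 1)
  # replicate estimate with another seed stays within a few MC SE
  ll2 <- loglikelihood(fit, d, mc_size = 10000, seed = 4)
  expect_lt(abs(ll$ofv - ll2$ofv), 5 * max(ll$mc_se, ll2$mc_se, 0.1))
})

test_that("standard errors are finite, positive and on a sane %RSE scale", {
  d <- table1_dataset(seed = 42, n = 8)
  fit <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                   settings = quick_settings(seed = 9)))
  fit <- fit_standard_errors(fit, occasion_data(d, 1), mc_size = 300, seed = 1)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  # fixed effects are identified at this scale; omegas/error can be noisier
  expect_true(all(fit$rse_pct[c("tk0", "v", "cl")] > 0 &
                    fit$rse_pct[c("tk0", "v", "cl")] < 200))
})

test_that("IWRES from the identity fit behave as standard normal residuals", {
  pop <- al_population_model("table1_day1")
  d <- generate_trial(recovery_design(n = 850), list(day1 = pop), seed = 20)
  # regenerate the observations without the zero floor: the identity-fit
  # residual is then exactly the generating N(0,1) draw
  tp <- attr(d, "true_params")
  obs <- d$EVID == 0
  withr::with_seed(77, {
    for (id in tp$ID) {
      sel <- obs & d$ID == id
      p <- structural_params(tp$tk0[tp$ID == id], tp$v[tp$ID == id],
                             tp$cl[tp$ID == id])
      f <- concentration(p, dose_schedule(0, 1000), d$TIME[sel])
      d$DV[sel] <- f + (0.36 + 0.32 * f) * rnorm(length(f))
      d$FLOOR[sel] <- 0L
    }
  })
  fit <- truth_fit(d, pop)
  g <- gof(fit, d)
  expect_equal(nrow(g), 850 * 12)
  ks <- suppressWarnings(stats::ks.test(g$iwres, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero-error data give identically zero residuals", {
  d <- generate_trial(recovery_design(n = 4),
                      list(day1 = degenerate_model()), seed = 3)
  fit <- truth_fit(d, degenerate_model())
  fit$err_a <- 1  # avoid 0/0 in the weighting; numerators are exact zeros
  g <- gof(fit, d)
  expect_true(all(abs(g$iwres) < 1e-10))
  expect_true(all(abs(g$pwres) < 1e-10))
  # plot-data tables round-trip to CSV
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(g, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(g), tolerance = 1e-12)
})

test_that("VPC rejects tiny replicate counts and is calibrated on self-simulated data", {
  pop <- al_population_model("table1_day1")
  d <- generate_trial(recovery_design(n = 16), list(day1 = pop), seed = 31)
  fit <- truth_fit(d, pop)
  expect_error(vpc(fit, d, n_replicates = 1), "at least 100")
  v <- vpc(fit, d, n_replicates = 200, seed = 2)
  med <- v[v$percentile == 50, ]
  expect_gte(sum(med$within_band), 11)
})

test_that("VPC bands widen when the between-subject variability doubles", {
  pop <- al_population_model("table1_day1")
  d <- generate_trial(recovery_design(n = 16), list(day1 = pop), seed = 32)
  fit <- truth_fit(d, pop)
  wide_pop <- population_model(
    tk0 = param_dist(0.85, 2 * 0.51, "lognormal"),
    v = param_dist(42.82, 2 * 13.2, "normal"),
    cl = param_dist(20.9, 2 * 0.54, "lognormal"),
    err_a = 0.36, err_b = 0.32, label = "wide")
  fit2 <- truth_fit(d, wide_pop)
  v1 <- vpc(fit, d, n_replicates = 150, seed = 3)
  v2 <- vpc(fit2, d, n_replicates = 150, seed = 3)
  hi1 <- v1[v1$percentile == 95 & v1$time > 0, ]
  hi2 <- v2[v2$percentile == 95 & v2$time > 0, ]
  expect_true(mean(hi2$sim_hi - hi2$sim_lo) > mean(hi1$sim_hi - hi1$sim_lo))
})

test_that("covariate screening handles empty and constant candidates", {
  d <- table1_dataset(seed = 42)
  fit <- suppressWarnings(saem_fit(occasion_data(d, 1),
                                   settings = quick_settings(seed = 9)))
  empty <- covariate_screen(fit, d, candidates = character(0))
  expect_identical(nrow(empty), 0L)
  d2 <- d; d2$SEX <- 1
  scr <- suppressWarnings(
    covariate_screen(fit, d2, candidates = "SEX",
                     settings = quick_settings(seed = 1), mc_size = 200))
  expect_match(scr$note[1], "constant")
  expect_true(is.na(scr$improving[1]))
  expect_error(covariate_screen(fit, d, candidates = "EGFR"), "EGFR")
})

test_that("a genuine weight-on-volume effect is detected by the screen", {
  d <- wt_effect_dataset(n = 32, exponent = 0.75, seed = 14)
  kinds <- c(tk0 = "lognormal", v = "lognormal", cl = "lognormal")
  fit <- suppressWarnings(saem_fit(d, kinds = kinds,
                                   settings = saem_settings(n_burn = 150,
                                                            n_smooth = 75,
                                                            seed = 3)))
  scr <- suppressWarnings(
    covariate_screen(fit, d, candidates = "WT",
                     settings = saem_settings(n_burn = 150, n_smooth = 75,
                                              seed = 4),
                     mc_size = 1000, seed = 5))
  wt_v <- scr[scr$parameter == "v", ]
  expect_true(wt_v$improving)
  expect_equal(wt_v$beta, 0.75, tolerance = 0.5)
})
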