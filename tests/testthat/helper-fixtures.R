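# Shared fixtures: all data are generated in code at test time.

quick_settings <- function(seed = 1, n_burn = 80, n_smooth = 40, ...) {
  saem_settings(n_burn = n_burn, n_smooth = n_smooth, seed = seed, ...)
}

# Single-occasion PK design at the study scale: n subjects, one oral dose,
# the 12 sampling times over 0-8 h.
recovery_design <- function(n = 16, dose_mg = 1000) {
  trial_design(arms = list(
    trial_arm("g", n, rep(dose_mg, 1), pk_days = 1)))
}

table1_dataset <- function(seed = 42, n = 16, dose_mg = 1000) {
  generate_trial(recovery_design(n, dose_mg),
                 models = list(day1 = al_population_model("table1_day1")),
                 seed = seed)
}

# A noise-free, variability-free version of a preset model.
degenerate_model <- function(base = al_population_model("table1_day1")) {
  population_model(
    tk0 = param_dist(base$tk0$typical, 0, base$tk0$kind),
    v = param_dist(base$v$typical, 0, base$v$kind),
    cl = param_dist(base$cl$typical, 0, base$cl$kind),
    err_a = 0, err_b = 0, label = base$label)
}

# Build a fit-shaped object at known true values (for diagnostics that
# need the "identity fit": model parameters and individual parameters set
# to the generating truth).
truth_fit <- function(data, pop, kinds = c(tk0 = pop$tk0$kind,
                                           v = pop$v$kind,
                                           cl = pop$cl$kind)) {
  tp <- attr(data, "true_params")
  stopifnot(!is.null(tp))
  tp <- tp[order(tp$ID), ]
  phi <- cbind(
    if (kinds[["tk0"]] == "lognormal") log(tp$tk0) else tp$tk0,
    if (kinds[["v"]] == "lognormal") log(tp$v) else tp$v,
    if (kinds[["cl"]] == "lognormal") log(tp$cl) else tp$cl)
  typ <- c(pop$tk0$typical, pop$v$typical, pop$cl$typical)
  mu <- ifelse(kinds == "lognormal", log(typ), typ)
  omega <- c(pop$tk0$omega, pop$v$omega, pop$cl$omega)
  structure(list(
    model = pop, kinds = kinds, mu_phi = unname(mu),
    omega = stats::setNames(pmax(omega, 1e-6), c("tk0", "v", "cl")),
    err_a = pop$err_a, err_b = pop$err_b, beta = NULL,
    n_params = 8L, phi_modes = phi,
    eta_modes = sweep(phi, 2, mu),
    subjects = sort(unique(tp$ID)), n_subj = nrow(tp),
    n_obs = sum(data$EVID == 0), trajectory = NULL, converged = TRUE,
    se = NULL, rse_pct = NULL, ofv = NULL,
    settings = saem_settings()), class = "saem_fit")
}

# Dataset with a genuine weight-on-volume power effect, for screening
# power checks.  All parameters lognormal so the power model is exact.
wt_effect_dataset <- function(n = 32, exponent = 0.75, seed = 1) {
  times <- c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n)) {
      wt <- rnorm(1, 58, 9)
      tk0 <- 0.85 * exp(rnorm(1, 0, 0.3))
      v <- 42.82 * (wt / 58)^exponent * exp(rnorm(1, 0, 0.15))
      cl <- 20.9 * exp(rnorm(1, 0, 0.3))
      p <- structural_params(tk0, v, cl)
      f <- concentration(p, dose_schedule(0, 1000), times)
      y <- pmax(f + (0.36 + 0.1 * f) * rnorm(length(f)), 0)
      rows[[i]] <- tibble::tibble(
        ID = i, OCC = 1, TIME = c(0, times),
        AMT = c(1000, rep(NA_real_, length(times))),
        DV = c(NA_real_, y),
        EVID = c(1L, rep(0L, length(times))),
        MDV = c(1L, rep(0L, length(times))),
        FLOOR = 0L, SEX = 1, AGE = 60, WT = wt, HT = 160)
    }
    dplyr::bind_rows(rows)
  })
}
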