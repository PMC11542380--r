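# Replicate parameter-recovery experiment at the study scale.

#' Parameter-recovery study at the trial's PK design
#'
#' Repeatedly generates a single-occasion dataset at the study scale
#' (default: 16 subjects, one 1,000-mg dose, the 12 sampling times over
#' 0-8 h) from a truth population model, fits each replicate by SAEM,
#' and tabulates the estimates next to the truth.
#'
#' @param truth A [population_model()] used to generate (default the
#'   day-1 preset).
#' @param n_replicates Number of replicate datasets (default 20).
#' @param n_subjects Subjects per replicate (default 16).
#' @param dose_mg Single oral dose (default 1000).
#' @param kinds Distribution-kind assignment for the fits (default
#'   matches the truth model's kinds).
#' @param settings [saem_settings()] template; replicate r uses
#'   `seed + r` for both data generation and fitting.
#' @param seed Base integer seed.
#' @return A tibble with one row per replicate: `replicate`, estimates
#'   (`tk0`, `v`, `cl`, `omega_*`, `a`, `b`), truth columns (`*_true`)
#'   and `converged`.
#' @export
parameter_recovery_study <- function(truth = al_population_model("table1_day1"),
                                     n_replicates = 20, n_subjects = 16,
                                     dose_mg = 1000,
                                     kinds = c(tk0 = truth$tk0$kind,
                                               v = truth$v$kind,
                                               cl = truth$cl$kind),
                                     settings = saem_settings(),
                                     seed = 1) {
  design <- trial_design(arms = list(
    trial_arm("recovery", n_subjects, rep(dose_mg, 1), pk_days = 1)))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    d <- generate_trial(design, models = list(day1 = truth), seed = seed + r)
    st <- settings
    st$seed <- seed + 10000L + r
    fit <- saem_fit(occasion_data(d, 1), kinds = kinds, settings = st)
    rows[[r]] <- tibble::tibble(
      replicate = r,
      tk0 = fit$model$tk0$typical, v = fit$model$v$typical,
      cl = fit$model$cl$typical,
      omega_tk0 = fit$omega[["tk0"]], omega_v = fit$omega[["v"]],
      omega_cl = fit$omega[["cl"]],
      a = fit$err_a, b = fit$err_b,
      tk0_true = truth$tk0$typical, v_true = truth$v$typical,
      cl_true = truth$cl$typical,
      converged = fit$converged)
  }
  dplyr::bind_rows(rows)
}
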