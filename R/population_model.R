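# Inter-individual variability and residual error.

#' Distribution of one population parameter
#'
#' A population parameter with typical value and between-subject random
#' effect.  For `kind = "lognormal"` the individual value is
#' `typical * exp(eta)` with `eta ~ N(0, omega^2)` (omega on the log
#' scale); for `kind = "normal"` it is `typical + eta` (omega on the
#' natural scale) with positivity enforced by rejection sampling.
#'
#' @param typical Positive typical (population) value.
#' @param omega Non-negative standard deviation of the random effect.
#' @param kind `"lognormal"` or `"normal"`.
#'
#' @return An object of class `param_dist`.
#' @examples
#' param_dist(16.13, 0.38, "lognormal")
#' @export
param_dist <- function(typical, omega, kind = c("lognormal", "normal")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(typical), length(typical) == 1L, is.finite(typical),
            is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (typical <= 0) stop("`typical` must be strictly positive", call. = FALSE)
  if (omega < 0) stop("`omega` must be non-negative", call. = FALSE)
  structure(list(typical = typical, omega = omega, kind = kind),
            class = "param_dist")
}

#' Population pharmacokinetic model for one study occasion
#'
#' Bundles the three structural-parameter distributions with the combined
#' residual-error parameters for one occasion (sampling day).
#'
#' @param tk0,v,cl [param_dist()] objects for absorption duration (h),
#'   volume (L) and clearance (L/h).
#' @param err_a Additive residual SD (mg/L), non-negative.
#' @param err_b Proportional residual coefficient, non-negative.
#' @param label Occasion tag, e.g. `"day1"`.
#'
#' @return An object of class `population_model`.
#' @examples
#' al_population_model("table3_day28")
#' @export
population_model <- function(tk0, v, cl, err_a, err_b, label = "occasion") {
  stopifnot(inherits(tk0, "param_dist"), inherits(v, "param_dist"),
            inherits(cl, "param_dist"))
  if (!is.finite(err_a) || err_a < 0) stop("`err_a` must be >= 0", call. = FALSE)
  if (!is.finite(err_b) || err_b < 0) stop("`err_b` must be >= 0", call. = FALSE)
  structure(list(tk0 = tk0, v = v, cl = cl,
                 err_a = err_a, err_b = err_b, label = label),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %s\n", x$label))
  for (nm in c("tk0", "v", "cl")) {
    d <- x[[nm]]
    cat(sprintf("  %-3s typical %-8.4g omega %-7.4g (%s, CV %.1f%%)\n",
                nm, d$typical, d$omega, d$kind, implied_cv(d)))
  }
  cat(sprintf("  residual error a = %.4g mg/L, b = %.4g\n", x$err_a, x$err_b))
  invisible(x)
}

#' Bundled population-model presets
#'
#' The three fitted occasion models of total AL bioactivity: the 1,000-mg
#' arm on day 1 (`table1_day1`), and the titration arm on day 14
#' (`table2_day14`) and day 28 (`table3_day28`).
#' Distribution kinds follow the convention that reproduces the reported
#' coefficients of variation: absorption duration and clearance are
#' lognormal throughout; volume is normal on days 1 and 14 and lognormal
#' on day 28.
#'
#' @param name One of `"table1_day1"`, `"table2_day14"`, `"table3_day28"`.
#' @return A [population_model()] for `al_population_model()`, or a named
#'   list of all three for `al_model_presets()`.
#' @examples
#' al_model_presets()[["table1_day1"]]
#' @export
al_population_model <- function(name = c("table1_day1", "table2_day14", "table3_day28")) {
  name <- match.arg(name)
  switch(name,
    table1_day1 = population_model(
      tk0 = param_dist(0.85, 0.51, "lognormal"),
      v   = param_dist(42.82, 13.2, "normal"),
      cl  = param_dist(20.9, 0.54, "lognormal"),
      err_a = 0.36, err_b = 0.32, label = "day1"),
    table2_day14 = population_model(
      tk0 = param_dist(1.11, 0.35, "lognormal"),
      v   = param_dist(32.57, 8.89, "normal"),
      cl  = param_dist(17.2, 0.44, "lognormal"),
      err_a = 1.39, err_b = 0.17, label = "day14"),
    table3_day28 = population_model(
      tk0 = param_dist(0.95, 0.28, "lognormal"),
      v   = param_dist(32, 0.25, "lognormal"),
      cl  = param_dist(16.13, 0.38, "lognormal"),
      err_a = 2.21, err_b = 0.084, label = "day28"))
}

#' @rdname al_population_model
#' @export
al_model_presets <- function() {
  nms <- c("table1_day1", "table2_day14", "table3_day28")
  stats::setNames(lapply(nms, al_population_model), nms)
}

#' Map random effects to individual structural parameters
#'
#' @param pop A [population_model()].
#' @param eta Numeric length-3 vector of random effects, ordered
#'   (tk0, v, cl).
#' @return A [structural_params()] object.
#' @examples
#' individual_params(al_population_model("table3_day28"), c(0, 0, 0))
#' @export
individual_params <- function(pop, eta) {
  stopifnot(inherits(pop, "population_model"),
            is.numeric(eta), length(eta) == 3L, all(is.finite(eta)))
  val <- numeric(3)
  for (j in seq_len(3)) {
    d <- pop[[c("tk0", "v", "cl")[j]]]
    val[j] <- if (d$kind == "lognormal") d$typical * exp(eta[j]) else d$typical + eta[j]
    if (val[j] <= 0) {
      stop("random effect eta[", j, "] = ", eta[j],
           " yields a non-positive ", c("tk0", "v", "cl")[j],
           "; normal-kind draws must be resampled, not clipped", call. = FALSE)
    }
  }
  structural_params(val[1], val[2], val[3])
}

# Vectorised eta -> parameter transform used by samplers; assumes
# positivity already enforced.
param_values <- function(pop, eta_mat) {
  out <- matrix(NA_real_, nrow(eta_mat), 3,
                dimnames = list(NULL, c("tk0", "v", "cl")))
  for (j in seq_len(3)) {
    d <- pop[[c("tk0", "v", "cl")[j]]]
    out[, j] <- if (d$kind == "lognormal") d$typical * exp(eta_mat[, j])
                else d$typical + eta_mat[, j]
  }
  out
}

#' Sample virtual patients from a population model
#'
#' Random effects are independent, `eta_j ~ N(0, omega_j^2)`.  For
#' normal-kind parameters, draws producing a non-positive value are
#' resampled (up to 1000 retries per draw), never clipped.
#'
#' @param pop A [population_model()].
#' @param n Number of patients (>= 1).
#' @param seed Optional integer seed; sampling is deterministic given it.
#' @return A tibble with columns `id`, `eta_tk0`, `eta_v`, `eta_cl`,
#'   `tk0`, `v`, `cl`.
#' @examples
#' sample_patients(al_population_model("table3_day28"), 5, seed = 1)
#' @export
sample_patients <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  draw <- function() {
    eta <- matrix(0, n, 3)
    for (j in seq_len(3)) {
      d <- pop[[c("tk0", "v", "cl")[j]]]
      if (d$omega == 0) next
      e <- stats::rnorm(n, 0, d$omega)
      if (d$kind == "normal") {
        bad <- d$typical + e <= 0
        tries <- 0L
        while (any(bad)) {
          tries <- tries + 1L
          if (tries > 1000L) stop("positivity resampling exceeded 1000 retries",
                                  call. = FALSE)
          e[bad] <- stats::rnorm(sum(bad), 0, d$omega)
          bad <- d$typical + e <= 0
        }
      }
      eta[, j] <- e
    }
    eta
  }
  eta <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  vals <- param_values(pop, eta)
  tibble::tibble(id = seq_len(n),
                 eta_tk0 = eta[, 1], eta_v = eta[, 2], eta_cl = eta[, 3],
                 tk0 = vals[, 1], v = vals[, 2], cl = vals[, 3])
}

#' Coefficient of variation implied by a parameter distribution
#'
#' Lognormal: `100 * sqrt(exp(omega^2) - 1)`; normal:
#' `100 * omega / typical`.  This is the convention under which the
#' reported per-parameter %CV values are mutually consistent with the
#' reported omegas.
#'
#' @param dist A [param_dist()].
#' @return CV in percent.
#' @examples
#' implied_cv(param_dist(42.82, 13.2, "normal"))  # 30.83
#' @export
implied_cv <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  if (dist$omega == 0) return(0)
  if (dist$kind == "lognormal") 100 * sqrt(exp(dist$omega^2) - 1)
  else 100 * dist$omega / dist$typical
}

#' Apply combined residual error to true concentrations
#'
#' Combined error model `y = f + g(f) * eps`, `eps ~ N(0, 1)`, with
#' `g(f) = a + b f` (variant `"combined1"`, the default) or
#' `g(f) = sqrt(a^2 + b^2 f^2)` (variant `"combined2"`).  Negative draws
#' are floored at 0 and flagged rather than dropped.
#'
#' @param true_conc Numeric vector of model concentrations (mg/L), >= 0.
#' @param pop A [population_model()] supplying `err_a`, `err_b`.
#' @param seed Optional integer seed.
#' @param variant `"combined1"` or `"combined2"`.
#' @return A tibble with columns `conc` (observed, floored at 0) and
#'   `below_floor` (logical).
#' @export
residual_observe <- function(true_conc, pop, seed = NULL,
                             variant = c("combined1", "combined2")) {
  variant <- match.arg(variant)
  stopifnot(inherits(pop, "population_model"))
  if (any(true_conc < 0)) stop("`true_conc` must be non-negative", call. = FALSE)
  g <- if (variant == "combined1") pop$err_a + pop$err_b * true_conc
       else sqrt(pop$err_a^2 + pop$err_b^2 * true_conc^2)
  draw <- function() stats::rnorm(length(true_conc), 0, 1)
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  y <- true_conc + g * eps
  tibble::tibble(conc = pmax(y, 0), below_floor = y < 0)
}

#' Read or write a population model as a YAML config
#'
#' Serialises typical values, omegas, explicit distribution-kind tags and
#' residual-error parameters.
#'
#' @param pop A [population_model()].
#' @param path File path.
#' @return `read_population_model()` returns a [population_model()];
#'   `write_population_model()` returns `path` invisibly.
#' @export
write_population_model <- function(pop, path) {
  stopifnot(inherits(pop, "population_model"))
  obj <- list(label = pop$label,
              parameters = lapply(pop[c("tk0", "v", "cl")], function(d) {
                list(typical = d$typical, omega = d$omega, kind = d$kind)
              }),
              error = list(a = pop$err_a, b = pop$err_b))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_population_model
#' @export
read_population_model <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("label", "parameters", "error")
  if (!all(need %in% names(obj))) {
    stop("model config must contain fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pd <- function(p) param_dist(p$typical, p$omega, p$kind)
  population_model(tk0 = pd(obj$parameters$tk0), v = pd(obj$parameters$v),
                   cl = pd(obj$parameters$cl),
                   err_a = obj$error$a, err_b = obj$error$b,
                   label = obj$label)
}
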