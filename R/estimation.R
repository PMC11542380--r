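# SAEM estimation of the population model from a trial dataset.
#
# Individual parameters are handled on the phi scale: phi_j = log(p_j) for
# lognormal-kind parameters and phi_j = p_j for normal-kind ones, so that
# phi ~ N(mu, diag(omega^2)) in both cases and omega carries the reported
# convention directly.

PARAM_NAMES <- c("tk0", "v", "cl")

#' SAEM run settings
#'
#' The stochastic approximation schedule uses step size 1 during the
#' exploratory phase (`n_burn` iterations) and `1/(iter - n_burn)` during
#' the smoothing phase (`n_smooth` iterations).  The Metropolis proposal
#' SD is adapted during the exploratory phase towards 30-50% acceptance.
#'
#' @param n_burn Exploratory iterations (>= 1), default 300.
#' @param n_smooth Smoothing iterations (>= 1), default 200.
#' @param mcmc_steps Metropolis passes per subject per iteration, default 2.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param init Optional named list of initial values (any of `tk0`, `v`,
#'   `cl`, `omega` (length 3), `a`, `b`); unspecified entries come from a
#'   pooled nonlinear least-squares fit and defaults.
#' @param adapt_interval Iterations between proposal adaptations.
#' @return A list of class `saem_settings`.
#' @export
saem_settings <- function(n_burn = 300, n_smooth = 200, mcmc_steps = 2,
                          seed = 1, init = NULL, adapt_interval = 20) {
  stopifnot(n_burn >= 1, n_smooth >= 1, mcmc_steps >= 1, adapt_interval >= 1)
  structure(list(n_burn = as.integer(n_burn), n_smooth = as.integer(n_smooth),
                 mcmc_steps = as.integer(mcmc_steps), seed = as.integer(seed),
                 init = init, adapt_interval = as.integer(adapt_interval)),
            class = "saem_settings")
}

# Internal: index a dataset into the structures the samplers need.
prepare_nlme_data <- function(data) {
  stopifnot(is.data.frame(data))
  if ("OCC" %in% names(data) && length(unique(data$OCC)) > 1L) {
    stop("dataset spans several occasions; fit one at a time (see occasion_data())",
         call. = FALSE)
  }
  ids <- sort(unique(data$ID))
  n_subj <- length(ids)
  if (n_subj < 2L) stop("at least 2 subjects are required", call. = FALSE)
  obs <- data[data$EVID == 0 & data$MDV == 0 & !is.na(data$DV), , drop = FALSE]
  per_subj <- table(factor(obs$ID, levels = ids))
  if (any(per_subj < 4)) {
    stop("every subject needs at least 4 observations", call. = FALSE)
  }
  dose <- data[data$EVID == 1, , drop = FALSE]
  obs_subj <- match(obs$ID, ids)
  dose_subj <- match(dose$ID, ids)
  # (observation, dose) pair expansion for superposition
  pair <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
    k <- which(dose_subj == obs_subj[i])
    cbind(obs = i, u = obs$TIME[i] - dose$TIME[k], amt = dose$AMT[k])
  }))
  list(ids = ids, n_subj = n_subj,
       obs_t = obs$TIME, obs_y = obs$DV, obs_subj = obs_subj,
       n_obs = nrow(obs),
       pair_obs = as.integer(pair[, "obs"]), pair_u = pair[, "u"],
       pair_amt = pair[, "amt"], pair_subj = obs_subj[pair[, "obs"]],
       covariates = data[!duplicated(data$ID), c("ID", intersect(
         c("SEX", "AGE", "WT", "HT"), names(data))), drop = FALSE],
       occ = if ("OCC" %in% names(data)) unique(data$OCC) else NA_integer_)
}

phi_to_params <- function(phi, kinds) {
  p <- phi
  for (j in seq_len(3)) if (kinds[PARAM_NAMES[j]] == "lognormal") p[, j] <- exp(phi[, j])
  p
}

# Model predictions for all observations given an n_subj x 3 parameter matrix.
predict_f <- function(prep, params) {
  tk0 <- params[prep$pair_subj, 1]
  v <- params[prep$pair_subj, 2]
  cl <- params[prep$pair_subj, 3]
  ke <- cl / v
  u <- prep$pair_u
  contrib <- (prep$pair_amt / (tk0 * cl)) *
    (1 - exp(-ke * pmin(u, tk0))) * exp(-ke * pmax(u - tk0, 0))
  contrib[u < 0 | prep$pair_amt == 0] <- 0
  as.vector(rowsum(contrib, prep$pair_obs, reorder = TRUE))
}

# Per-subject Gaussian log-likelihood of the observations; -Inf where the
# parameter vector is invalid.
ll_by_subject <- function(prep, phi, kinds, a, b) {
  params <- phi_to_params(phi, kinds)
  bad <- rowSums(params <= 0 | !is.finite(params)) > 0
  params[bad, ] <- 1  # placeholder, overwritten with -Inf below
  f <- predict_f(prep, params)
  g <- pmax(a + b * f, 1e-6)
  llo <- -log(g) - 0.5 * ((prep$obs_y - f) / g)^2
  ll <- as.vector(rowsum(llo, prep$obs_subj, reorder = TRUE))
  ll[bad] <- -Inf
  list(ll = ll, f = f)
}

# Pooled naive NLS of the typical-value model (multi-start Nelder-Mead).
pooled_nls <- function(prep) {
  sse <- function(lp) {
    p <- exp(lp)
    params <- matrix(p, prep$n_subj, 3, byrow = TRUE)
    sum((prep$obs_y - predict_f(prep, params))^2)
  }
  starts <- expand.grid(tk0 = c(0.5, 1.5), v = c(20, 60), cl = c(10, 30))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(log(as.numeric(starts[i, ])), sse,
                      control = list(maxit = 300))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish the winning start to tight tolerance
  best <- stats::optim(best$par, sse,
                       control = list(maxit = 2000, reltol = 1e-14))
  stats::setNames(exp(best$par), PARAM_NAMES)
}

#' Fit the population model by SAEM
#'
#' Stochastic approximation EM: the E-step runs componentwise Metropolis
#' random-walk updates of every subject's individual parameters (phi
#' scale) targeting their conditional posterior; the M-step updates the
#' population means and omegas from stochastically-approximated sufficient
#' statistics, and the combined-error parameters (a, b) by conditional
#' maximum likelihood given the current individual parameters, smoothed
#' with the same step sizes.  Deterministic given `settings$seed`.
#'
#' @param data A single-occasion dataset tibble (see [occasion_data()]).
#' @param kinds Named character vector assigning `"lognormal"` or
#'   `"normal"` to each of `tk0`, `v`, `cl`.
#' @param settings A [saem_settings()].
#' @param covariate Optional covariate extension for one parameter:
#'   a list with `param` (one of `"tk0"`, `"v"`, `"cl"`), `x` (numeric,
#'   one value per subject in `ID` order) and `name`.  The mean of that
#'   parameter's phi becomes `mu + beta * x` (a power model on the
#'   covariate when `x` is a centred log covariate and the parameter is
#'   lognormal).
#' @return A `saem_fit` object: the estimated [population_model()]
#'   (`$model`), `$omega`, `$err_a`, `$err_b`, per-subject random-effect
#'   modes (`$eta_modes`), the convergence trajectory (`$trajectory`),
#'   a `$converged` flag and bookkeeping.  `%RSE`/SE slots are filled by
#'   [fit_standard_errors()]; the OFV slot by [loglikelihood()].
#' @export
saem_fit <- function(data,
                     kinds = c(tk0 = "lognormal", v = "normal", cl = "lognormal"),
                     settings = saem_settings(),
                     covariate = NULL) {
  stopifnot(inherits(settings, "saem_settings"))
  kinds <- kinds[PARAM_NAMES]
  if (!all(kinds %in% c("lognormal", "normal"))) {
    stop("`kinds` must assign 'lognormal' or 'normal' to tk0, v, cl",
         call. = FALSE)
  }
  prep <- prepare_nlme_data(data)
  N <- prep$n_subj
  has_cov <- !is.null(covariate)
  if (has_cov) {
    stopifnot(covariate$param %in% PARAM_NAMES, length(covariate$x) == N)
    jc <- match(covariate$param, PARAM_NAMES)
    x <- covariate$x
    sx <- mean(x); sx2 <- mean(x^2)
    if (sx2 - sx^2 < 1e-12) stop("constant covariate", call. = FALSE)
  }

  withr::with_seed(settings$seed, {
    # --- initial values ------------------------------------------------
    typ0 <- pooled_nls(prep)
    init <- settings$init
    for (nm in PARAM_NAMES) if (!is.null(init[[nm]])) typ0[nm] <- init[[nm]]
    mu <- ifelse(kinds == "lognormal", log(typ0), typ0)
    omega <- if (!is.null(init$omega)) init$omega else
      ifelse(kinds == "lognormal", 0.3, 0.3 * typ0)
    a <- if (!is.null(init$a)) init$a else max(0.1 * mean(prep$obs_y), 1e-3)
    b <- if (!is.null(init$b)) init$b else 0.2
    beta <- 0

    n_iter <- settings$n_burn + settings$n_smooth
    phi <- matrix(rep(mu, each = N), N, 3)
    prop_sd <- pmax(omega, c(0.1, 0.1, 0.1))
    cur <- ll_by_subject(prep, phi, kinds, a, b)
    llc <- cur$ll
    acc_cnt <- numeric(3); acc_tot <- numeric(3)
    s1 <- mu; s2 <- mu^2 + omega^2; sxp <- if (has_cov) mean(x * phi[, jc]) else 0
    omega_floored <- FALSE
    traj <- matrix(NA_real_, n_iter, 8,
                   dimnames = list(NULL, c("tk0", "v", "cl",
                                           "omega_tk0", "omega_v", "omega_cl",
                                           "a", "b")))

    mean_phi <- function() {
      m <- matrix(rep(mu, each = N), N, 3)
      if (has_cov) m[, jc] <- m[, jc] + beta * x
      m
    }

    for (iter in seq_len(n_iter)) {
      m <- mean_phi()
      # --- E-step: Metropolis within Gibbs ----------------------------
      for (pass in seq_len(settings$mcmc_steps)) {
        for (j in seq_len(3)) {
          prop <- phi
          prop[, j] <- phi[, j] + stats::rnorm(N, 0, prop_sd[j])
          new <- ll_by_subject(prep, prop, kinds, a, b)
          logr <- (new$ll - llc) -
            0.5 * ((prop[, j] - m[, j])^2 - (phi[, j] - m[, j])^2) /
            pmax(omega[j]^2, 1e-12)
          take <- log(stats::runif(N)) < logr
          phi[take, j] <- prop[take, j]
          llc[take] <- new$ll[take]
          acc_cnt[j] <- acc_cnt[j] + sum(take)
          acc_tot[j] <- acc_tot[j] + N
        }
      }
      if (iter <= settings$n_burn && iter %% settings$adapt_interval == 0) {
        rate <- acc_cnt / acc_tot
        prop_sd[rate > 0.5] <- prop_sd[rate > 0.5] * 1.4
        prop_sd[rate < 0.3] <- prop_sd[rate < 0.3] / 1.4
        acc_cnt[] <- 0; acc_tot[] <- 0
      }

      # --- M-step with stochastic approximation -----------------------
      gam <- if (iter <= settings$n_burn) 1 else 1 / (iter - settings$n_burn)
      s1 <- s1 + gam * (colMeans(phi) - s1)
      s2 <- s2 + gam * (colMeans(phi^2) - s2)
      if (has_cov) sxp <- sxp + gam * (mean(x * phi[, jc]) - sxp)

      mu <- s1
      varj <- pmax(s2 - s1^2, 1e-12)
      # simulated annealing: during exploration the random-effect and
      # residual variances may shrink by at most 5% per iteration, which
      # prevents premature collapse while the chains still mix
      anneal <- iter <= settings$n_burn
      if (has_cov) {
        beta <- unname((sxp - sx * s1[jc]) / (sx2 - sx^2))
        mu[jc] <- s1[jc] - beta * sx
        varj[jc] <- pmax(s2[jc] - 2 * mu[jc] * s1[jc] - 2 * beta * sxp +
                           mu[jc]^2 + 2 * mu[jc] * beta * sx + beta^2 * sx2,
                         1e-12)
      }
      if (anneal) varj <- pmax(varj, 0.95 * omega^2)
      omega <- sqrt(varj)
      if (!anneal && any(omega < 1e-6)) {
        omega <- pmax(omega, 1e-6); omega_floored <- TRUE
      }
      omega <- pmax(omega, 1e-6)

      # error parameters: conditional ML given current phi, SA-smoothed
      f_cur <- ll_by_subject(prep, phi, kinds, a, b)$f
      r <- prep$obs_y - f_cur
      err_obj <- function(lab) {
        g <- pmax(exp(lab[1]) + exp(lab[2]) * f_cur, 1e-8)
        sum(log(g) + 0.5 * r^2 / g^2)
      }
      eo <- stats::optim(log(pmax(c(a, b), 1e-8)), err_obj,
                         control = list(maxit = 40))
      a_new <- exp(eo$par[1]); b_new <- exp(eo$par[2])
      if (anneal) {
        # bounded moves during exploration: at most -2.5%/+5% per
        # iteration, which both prevents premature collapse and breaks
        # the runaway where MH scatter is re-absorbed as residual error
        a_new <- min(max(a_new, 0.975 * a), 1.05 * a)
        b_new <- min(max(b_new, 0.975 * b), 1.05 * b)
      }
      a <- a + gam * (a_new - a)
      b <- b + gam * (b_new - b)
      llc <- ll_by_subject(prep, phi, kinds, a, b)$ll

      typ <- ifelse(kinds == "lognormal", exp(mu), mu)
      traj[iter, ] <- c(typ, omega, a, b)
    }
    if (omega_floored) {
      warning("one or more omegas collapsed and were floored at 1e-6",
              call. = FALSE)
    }

    # --- convergence diagnostic on the trajectory tail ------------------
    tail_n <- min(50L, settings$n_smooth)
    tail_idx <- seq(n_iter - tail_n + 1L, n_iter)
    rel_sd <- apply(traj[tail_idx, 1:3, drop = FALSE], 2,
                    function(z) stats::sd(z) / max(abs(mean(z)), 1e-12))
    converged <- all(rel_sd < 0.02)
    if (!converged) {
      warning("SAEM trajectory still moving over the last ", tail_n,
              " iterations (max relative SD ", signif(max(rel_sd), 3),
              "); returning the partial result", call. = FALSE)
    }

    typ <- ifelse(kinds == "lognormal", exp(mu), mu)
    model <- population_model(
      tk0 = param_dist(typ[1], omega[1], kinds[1]),
      v = param_dist(typ[2], omega[2], kinds[2]),
      cl = param_dist(typ[3], omega[3], kinds[3]),
      err_a = a, err_b = b,
      label = if (is.na(prep$occ)) "fit" else paste0("day", prep$occ))

    # --- empirical Bayes modes -----------------------------------------
    m <- mean_phi()
    phi_modes <- phi
    for (i in seq_len(N)) {
      nlj <- function(ph) {
        -subject_loglik(prep, i, matrix(ph, 1, 3), kinds, a, b) +
          0.5 * sum((ph - m[i, ])^2 / pmax(omega^2, 1e-12))
      }
      o <- stats::optim(phi[i, ], nlj, control = list(maxit = 300))
      phi_modes[i, ] <- o$par
    }
    eta_modes <- phi_modes - m
    colnames(eta_modes) <- PARAM_NAMES

    structure(list(model = model, kinds = kinds,
                   mu_phi = mu, omega = stats::setNames(omega, PARAM_NAMES),
                   err_a = a, err_b = b,
                   beta = if (has_cov) beta else NULL,
                   covariate = if (has_cov) covariate["param"] else NULL,
                   n_params = if (has_cov) 9L else 8L,
                   eta_modes = eta_modes, phi_modes = phi_modes,
                   subjects = prep$ids, n_subj = N, n_obs = prep$n_obs,
                   trajectory = tibble::as_tibble(traj),
                   converged = converged,
                   se = NULL, rse_pct = NULL, ofv = NULL,
                   settings = settings),
              class = "saem_fit")
  })
}

# Log-likelihood of subject i's observations for an M x 3 matrix of phi rows.
subject_loglik <- function(prep, i, phi_mat, kinds, a, b) {
  sel <- prep$pair_subj == i
  u <- prep$pair_u[sel]; amt <- prep$pair_amt[sel]
  oidx <- match(prep$pair_obs[sel], sort(unique(prep$pair_obs[sel])))
  y <- prep$obs_y[prep$obs_subj == i]
  p <- phi_mat
  for (j in seq_len(3)) if (kinds[j] == "lognormal") p[, j] <- exp(phi_mat[, j])
  bad <- rowSums(p <= 0 | !is.finite(p)) > 0
  M <- nrow(p)
  ll <- numeric(M)
  tk0 <- p[, 1]; v <- p[, 2]; cl <- p[, 3]; ke <- cl / v
  # n_i x M contribution matrices
  f <- matrix(0, length(y), M)
  for (k in seq_along(u)) {
    uk <- u[k]
    if (uk < 0 || amt[k] == 0) next
    contrib <- (amt[k] / (tk0 * cl)) *
      (1 - exp(-ke * pmin(uk, tk0))) * exp(-ke * pmax(uk - tk0, 0))
    f[oidx[k], ] <- f[oidx[k], ] + contrib
  }
  g <- pmax(a + b * f, 1e-6)
  ll <- colSums(-log(g) - 0.5 * ((y - f) / g)^2) - length(y) * 0.5 * log(2 * pi)
  ll[bad] <- -Inf
  ll
}

#' @export
print.saem_fit <- function(x, ...) {
  cat(sprintf("<saem_fit> %s: %d subjects, %d observations%s\n",
              x$model$label, x$n_subj, x$n_obs,
              if (x$converged) "" else " (NOT converged)"))
  print(x$model)
  if (!is.null(x$ofv)) cat(sprintf("  OFV = %.2f\n", x$ofv))
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Importance-sampling log-likelihood (OFV)
#'
#' Estimates -2 log-likelihood of the fitted model by importance sampling
#' around each subject's conditional mode, using a multivariate
#' t-distributed proposal (df 4) whose scale comes from the local Hessian.
#' A Monte-Carlo standard error accompanies the estimate.
#'
#' @param fit A [saem_fit()] result.
#' @param data The dataset the model was fitted to.
#' @param mc_size Importance samples per subject (>= 100).
#' @param seed Integer seed.
#' @return An object of class `ofv_estimate`: list with `ofv`, `mc_se`,
#'   `mc_size` and per-subject log-likelihood contributions.
#' @export
loglikelihood <- function(fit, data, mc_size = 10000, seed = 1) {
  stopifnot(inherits(fit, "saem_fit"))
  if (mc_size < 100) stop("`mc_size` must be at least 100", call. = FALSE)
  prep <- prepare_nlme_data(data)
  N <- prep$n_subj
  kinds <- fit$kinds; a <- fit$err_a; b <- fit$err_b
  omega <- pmax(fit$omega, 1e-6)
  m <- matrix(rep(fit$mu_phi, each = N), N, 3)
  if (!is.null(fit$beta)) stop("OFV for covariate fits: supply x via covariate refit interface", call. = FALSE)

  withr::with_seed(seed, {
    logLi <- numeric(N); se2 <- numeric(N)
    for (i in seq_len(N)) {
      nlp <- function(ph) {
        -(subject_loglik(prep, i, matrix(ph, 1, 3), kinds, a, b) -
            0.5 * sum((ph - m[i, ])^2 / omega^2) - sum(log(omega)) -
            1.5 * log(2 * pi))
      }
      o <- stats::optim(fit$phi_modes[i, ], nlp, control = list(maxit = 500))
      H <- stats::optimHess(o$par, nlp)
      eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
      lam <- pmax(eh$values, 1e-4)
      Sig <- eh$vectors %*% diag(1 / lam) %*% t(eh$vectors)
      L <- t(chol(Sig))
      nu <- 4; d <- 3
      z <- matrix(stats::rnorm(mc_size * d), mc_size, d)
      w <- stats::rchisq(mc_size, nu) / nu
      uu <- z / sqrt(w)
      phs <- sweep(uu %*% t(L), 2, o$par, "+")
      lq <- lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
        ((nu + d) / 2) * log1p(rowSums(uu^2) / nu) - sum(log(diag(L)))
      lp <- subject_loglik(prep, i, phs, kinds, a, b) -
        0.5 * colSums((t(phs) - m[i, ])^2 / omega^2) - sum(log(omega)) -
        1.5 * log(2 * pi)
      lw <- lp - lq
      logLi[i] <- log_sum_exp(lw) - log(mc_size)
      wn <- exp(lw - max(lw)); wn <- wn / sum(wn)
      se2[i] <- sum(wn^2) - 1 / mc_size  # variance of the self-normalised mean
      se2[i] <- max(se2[i], 0)
    }
    structure(list(ofv = -2 * sum(logLi),
                   mc_se = 2 * sqrt(sum(se2)),
                   mc_size = mc_size, logLi = logLi),
              class = "ofv_estimate")
  })
}

#' @export
print.ofv_estimate <- function(x, ...) {
  cat(sprintf("OFV = %.3f (MC SE %.3f, %d samples/subject)\n",
              x$ofv, x$mc_se, x$mc_size))
  invisible(x)
}

#' Standard errors of the population estimates
#'
#' Numerical Fisher-information approximation: central-difference Hessian
#' of the importance-sampling log-likelihood over the 8 population
#' parameters, with common random numbers across evaluations.  Returns the
#' fit with `$se` and `$rse_pct` filled (natural scale; %RSE =
#' 100 * SE / estimate).
#'
#' @param fit A [saem_fit()] result (without covariate extension).
#' @param data The fitted dataset.
#' @param mc_size Importance samples per evaluation.
#' @param seed Integer seed (shared across evaluations).
#' @param rel_step Relative finite-difference step.
#' @return The fit, augmented.
#' @export
fit_standard_errors <- function(fit, data, mc_size = 1000, seed = 1,
                                rel_step = 0.05) {
  stopifnot(inherits(fit, "saem_fit"), is.null(fit$beta))
  prep <- prepare_nlme_data(data)
  kinds <- fit$kinds
  N <- prep$n_subj
  # theta on an unconstrained-ish working scale
  theta <- c(fit$mu_phi, log(pmax(fit$omega, 1e-6)),
             log(max(fit$err_a, 1e-8)), log(max(fit$err_b, 1e-8)))

  # one fixed importance sampler per subject, built at the estimates, so
  # that the finite-difference objective is smooth in theta (common draws)
  omega0 <- pmax(fit$omega, 1e-6)
  m0 <- matrix(rep(fit$mu_phi, each = N), N, 3)
  samplers <- withr::with_seed(seed, lapply(seq_len(N), function(i) {
    nlp <- function(ph) {
      -(subject_loglik(prep, i, matrix(ph, 1, 3), kinds, fit$err_a, fit$err_b) -
          0.5 * sum((ph - m0[i, ])^2 / omega0^2))
    }
    o <- stats::optim(fit$phi_modes[i, ], nlp, control = list(maxit = 500))
    H <- stats::optimHess(o$par, nlp)
    eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- pmax(eh$values, 1e-4)
    L <- t(chol(eh$vectors %*% diag(1.5 / lam) %*% t(eh$vectors)))
    nu <- 4; dd <- 3
    z <- matrix(stats::rnorm(mc_size * dd), mc_size, dd)
    w <- stats::rchisq(mc_size, nu) / nu
    uu <- z / sqrt(w)
    phs <- sweep(uu %*% t(L), 2, o$par, "+")
    lq <- lgamma((nu + dd) / 2) - lgamma(nu / 2) - (dd / 2) * log(nu * pi) -
      ((nu + dd) / 2) * log1p(rowSums(uu^2) / nu) - sum(log(diag(L)))
    list(phs = phs, lq = lq)
  }))

  ll_at <- function(th) {
    mu <- th[1:3]; om <- exp(th[4:6]); a <- exp(th[7]); b <- exp(th[8])
    tot <- 0
    for (i in seq_len(N)) {
      s <- samplers[[i]]
      lp <- subject_loglik(prep, i, s$phs, kinds, a, b) -
        0.5 * colSums((t(s$phs) - mu)^2 / om^2) - sum(log(om)) -
        1.5 * log(2 * pi)
      tot <- tot + log_sum_exp(lp - s$lq) - log(mc_size)
    }
    tot
  }
  k <- length(theta)
  f0 <- ll_at(theta)
  # calibrate per-coordinate steps to a comparable objective change, so
  # that mixed parameter scales do not corrupt the cross terms
  h <- pmax(abs(theta) * rel_step, 0.01)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h[i]
    curv <- abs(ll_at(theta + e) - 2 * f0 + ll_at(theta - e)) / h[i]^2
    if (is.finite(curv) && curv > 1e-8) {
      h[i] <- min(max(sqrt(0.2 / curv), 1e-4), 10 * h[i])
    }
  }
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h[i]
    H[i, i] <- (ll_at(theta + e) - 2 * f0 + ll_at(theta - e)) / h[i]^2
  }
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    ei <- numeric(k); ei[i] <- h[i]
    ej <- numeric(k); ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (ll_at(theta + ei + ej) - ll_at(theta + ei - ej) -
         ll_at(theta - ei + ej) + ll_at(theta - ei - ej)) /
      (4 * h[i] * h[j])
  }
  I <- -(H + t(H)) / 2
  ei <- eigen(I, symmetric = TRUE)
  lam <- pmax(ei$values, 1e-8)
  cov_theta <- ei$vectors %*% diag(1 / lam) %*% t(ei$vectors)
  se_theta <- sqrt(pmax(diag(cov_theta), 0))
  # delta method back to natural scale
  est <- c(ifelse(kinds == "lognormal", exp(fit$mu_phi), fit$mu_phi),
           fit$omega, fit$err_a, fit$err_b)
  jac <- c(ifelse(kinds == "lognormal", exp(fit$mu_phi), 1),
           fit$omega, fit$err_a, fit$err_b)
  se <- se_theta * abs(jac)
  names(se) <- names(est) <- c(PARAM_NAMES, paste0("omega_", PARAM_NAMES), "a", "b")
  fit$se <- se
  fit$rse_pct <- 100 * se / abs(est)
  fit
}

#' Model-selection information criteria
#'
#' `AIC = OFV + 2k`; `BIC = OFV + k log(N_subjects)`; the corrected BIC
#' uses a hybrid penalty in which parameters tied to random effects are
#' penalised by `log(N_subjects)` and the remaining (error/fixed-only)
#' parameters by `log(n_obs)`.
#'
#' @param ofv -2 log-likelihood.
#' @param n_params Total parameter count k (8 for the base occasion model:
#'   3 typicals + 3 omegas + a + b).
#' @param n_subjects,n_obs Counts (>= 1).
#' @param n_random_linked Parameters tied to random effects (default
#'   `n_params - 2`, i.e. all but the two error parameters; 0 when
#'   `n_params` is 0).
#' @return Named list with `AIC`, `BIC`, `BICc`.
#' @examples
#' information_criteria(100, 8, 16, 192)
#' @export
information_criteria <- function(ofv, n_params, n_subjects, n_obs,
                                 n_random_linked = max(n_params - 2, 0)) {
  stopifnot(n_subjects >= 1, n_obs >= 1, n_params >= 0,
            n_random_linked >= 0, n_random_linked <= n_params)
  k_f <- n_params - n_random_linked
  list(AIC = ofv + 2 * n_params,
       BIC = ofv + n_params * log(n_subjects),
       BICc = ofv + n_random_linked * log(n_subjects) + k_f * log(n_obs))
}

#' Forward covariate screening
#'
#' Adds one covariate at a time to each structural parameter (power model
#' on centred log continuous covariates; fractional shift on sex) and
#' refits by SAEM.  A candidate-parameter pair "improves" the model when
#' both `delta_BIC < 0` and `delta_OFV < -3.84` (chi-square, 1 df,
#' alpha = 0.05).
#'
#' @param fit Base [saem_fit()] (no covariate).
#' @param data The fitted dataset (must carry the candidate columns).
#' @param candidates Covariate column names to screen.
#' @param settings [saem_settings()] for the extension refits (defaults to
#'   a shortened schedule derived from the base fit's settings).
#' @param mc_size,seed Importance-sampling controls for the OFVs (shared
#'   between base and extended models).
#' @return A tibble with one row per candidate-parameter pair:
#'   `covariate`, `parameter`, `beta`, `delta_ofv`, `delta_bic`,
#'   `improving`, `note`.  Constant covariates are skipped with a note.
#' @export
covariate_screen <- function(fit, data,
                             candidates = c("SEX", "AGE", "WT", "HT"),
                             settings = NULL, mc_size = 1000, seed = 1) {
  stopifnot(inherits(fit, "saem_fit"))
  if (length(candidates) == 0) {
    return(tibble::tibble(covariate = character(), parameter = character(),
                          beta = numeric(), delta_ofv = numeric(),
                          delta_bic = numeric(), improving = logical(),
                          note = character()))
  }
  missing_cand <- setdiff(candidates, names(data))
  if (length(missing_cand)) {
    stop("candidate covariates absent from data: ",
         paste(missing_cand, collapse = ", "), call. = FALSE)
  }
  if (is.null(settings)) {
    settings <- saem_settings(
      n_burn = max(100L, fit$settings$n_burn %/% 2L),
      n_smooth = max(50L, fit$settings$n_smooth %/% 2L),
      mcmc_steps = fit$settings$mcmc_steps,
      seed = fit$settings$seed)
  }
  prep <- prepare_nlme_data(data)
  # refit the base model under the same (possibly shortened) screening
  # schedule so that delta-OFV compares like with like
  base <- if (identical(settings[c("n_burn", "n_smooth", "mcmc_steps")],
                        fit$settings[c("n_burn", "n_smooth", "mcmc_steps")])) {
    fit
  } else {
    saem_fit(data, kinds = fit$kinds, settings = settings)
  }
  base_ofv <- loglikelihood(base, data, mc_size = mc_size, seed = seed)$ofv
  logN <- log(fit$n_subj)

  rows <- list()
  for (cand in candidates) {
    vals <- prep$covariates[[cand]]
    if (length(unique(vals)) < 2L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = cand, parameter = NA_character_, beta = NA_real_,
        delta_ofv = NA_real_, delta_bic = NA_real_, improving = NA,
        note = "constant covariate; skipped")
      next
    }
    x <- if (cand == "SEX") vals - mean(vals) else log(vals / stats::median(vals))
    for (par in PARAM_NAMES) {
      ext <- saem_fit(data, kinds = fit$kinds, settings = settings,
                      covariate = list(param = par, x = x, name = cand))
      # OFV of the extended model: integrate with the covariate-shifted mean
      ext_ofv <- covariate_ofv(ext, data, x, mc_size = mc_size, seed = seed)
      d_ofv <- ext_ofv - base_ofv
      d_bic <- d_ofv + logN  # one extra parameter
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = cand, parameter = par, beta = ext$beta,
        delta_ofv = d_ofv, delta_bic = d_bic,
        improving = (d_bic < 0) && (d_ofv < -3.84), note = "")
    }
  }
  dplyr::bind_rows(rows)
}

# OFV for a covariate-extended fit (mean of the target phi shifted by
# beta * x per subject).
covariate_ofv <- function(fit, data, x, mc_size = 1000, seed = 1) {
  prep <- prepare_nlme_data(data)
  N <- prep$n_subj
  kinds <- fit$kinds; a <- fit$err_a; b <- fit$err_b
  omega <- pmax(fit$omega, 1e-6)
  jc <- match(fit$covariate$param, PARAM_NAMES)
  m <- matrix(rep(fit$mu_phi, each = N), N, 3)
  m[, jc] <- m[, jc] + fit$beta * x
  withr::with_seed(seed, {
    logLi <- numeric(N)
    for (i in seq_len(N)) {
      nlp <- function(ph) {
        -(subject_loglik(prep, i, matrix(ph, 1, 3), kinds, a, b) -
            0.5 * sum((ph - m[i, ])^2 / omega^2) - sum(log(omega)) -
            1.5 * log(2 * pi))
      }
      o <- stats::optim(fit$phi_modes[i, ], nlp, control = list(maxit = 500))
      H <- stats::optimHess(o$par, nlp)
      eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
      lam <- pmax(eh$values, 1e-4)
      L <- t(chol(eh$vectors %*% diag(1 / lam) %*% t(eh$vectors)))
      nu <- 4; d <- 3
      z <- matrix(stats::rnorm(mc_size * d), mc_size, d)
      w <- stats::rchisq(mc_size, nu) / nu
      uu <- z / sqrt(w)
      phs <- sweep(uu %*% t(L), 2, o$par, "+")
      lq <- lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
        ((nu + d) / 2) * log1p(rowSums(uu^2) / nu) - sum(log(diag(L)))
      lp <- subject_loglik(prep, i, phs, kinds, a, b) -
        0.5 * colSums((t(phs) - m[i, ])^2 / omega^2) - sum(log(omega)) -
        1.5 * log(2 * pi)
      logLi[i] <- log_sum_exp(lp - lq) - log(mc_size)
    }
    -2 * sum(logLi)
  })
}

#' Goodness-of-fit tables
#'
#' Observed versus population and individual predictions, with weighted
#' residuals.  `IWRES = (y - f_ind) / (a + b f_ind)` at the empirical
#' Bayes modes; population residuals use the typical-parameter
#' predictions.
#'
#' @param fit A [saem_fit()] result.
#' @param data The fitted dataset.
#' @return A tibble: `id`, `time`, `dv`, `pred_pop`, `pred_ind`, `pwres`,
#'   `iwres`.
#' @export
gof <- function(fit, data) {
  stopifnot(inherits(fit, "saem_fit"))
  prep <- prepare_nlme_data(data)
  N <- prep$n_subj
  typ_phi <- matrix(rep(fit$mu_phi, each = N), N, 3)
  f_pop <- predict_f(prep, phi_to_params(typ_phi, fit$kinds))
  f_ind <- predict_f(prep, phi_to_params(fit$phi_modes, fit$kinds))
  g_pop <- pmax(fit$err_a + fit$err_b * f_pop, 1e-6)
  g_ind <- pmax(fit$err_a + fit$err_b * f_ind, 1e-6)
  tibble::tibble(id = prep$ids[prep$obs_subj], time = prep$obs_t,
                 dv = prep$obs_y, pred_pop = f_pop, pred_ind = f_ind,
                 pwres = (prep$obs_y - f_pop) / g_pop,
                 iwres = (prep$obs_y - f_ind) / g_ind)
}

#' Visual predictive check
#'
#' Simulates `n_replicates` datasets at the observed design under the
#' fitted model (fresh random effects and residual error, floored at 0)
#' and summarises, per observation-time bin, the spread of each requested
#' percentile against the observed percentile.
#'
#' @param fit A [saem_fit()] result.
#' @param data The fitted dataset.
#' @param n_replicates Simulation replicates (>= 100).
#' @param percentiles Percentiles to track, default `c(5, 50, 95)`.
#' @param seed Integer seed.
#' @return A tibble with one row per time bin and percentile: `time`,
#'   `percentile`, `sim_lo`/`sim_mid`/`sim_hi` (2.5%, 50%, 97.5% of the
#'   simulated percentile), `observed` and `within_band`.
#' @export
vpc <- function(fit, data, n_replicates = 200, percentiles = c(5, 50, 95),
                seed = 1) {
  stopifnot(inherits(fit, "saem_fit"))
  if (n_replicates < 100) stop("`n_replicates` must be at least 100", call. = FALSE)
  prep <- prepare_nlme_data(data)
  N <- prep$n_subj
  bins <- sort(unique(prep$obs_t))
  bin_of <- match(prep$obs_t, bins)
  qs <- percentiles / 100

  sim_q <- withr::with_seed(seed, {
    out <- array(NA_real_, c(n_replicates, length(bins), length(qs)))
    for (r in seq_len(n_replicates)) {
      pat <- sample_patients(fit$model, N)
      params <- as.matrix(pat[, c("tk0", "v", "cl")])
      f <- predict_f(prep, params)
      y <- pmax(f + (fit$err_a + fit$err_b * f) * stats::rnorm(length(f)), 0)
      for (bi in seq_along(bins)) {
        out[r, bi, ] <- stats::quantile(y[bin_of == bi], qs, names = FALSE)
      }
    }
    out
  })

  rows <- list()
  for (bi in seq_along(bins)) for (qi in seq_along(qs)) {
    band <- stats::quantile(sim_q[, bi, qi], c(0.025, 0.5, 0.975), names = FALSE)
    obs <- stats::quantile(prep$obs_y[bin_of == bi], qs[qi], names = FALSE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time = bins[bi], percentile = percentiles[qi],
      sim_lo = band[1], sim_mid = band[2], sim_hi = band[3],
      observed = obs, within_band = obs >= band[1] & obs <= band[3])
  }
  dplyr::bind_rows(rows)
}
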