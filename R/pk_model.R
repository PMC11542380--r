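# Structural model: one compartment, zero-order absorption without lag,
# linear elimination.  All times in hours, amounts in mg, volumes in L,
# concentrations in mg/L.

#' Structural pharmacokinetic parameters for one subject
#'
#' One-compartment model with zero-order (constant-rate) absorption of
#' duration `tk0` and linear clearance.  The elimination rate constant is
#' derived as `ke = cl / v`.
#'
#' @param tk0 Zero-order absorption duration (h), strictly positive.  A
#'   degenerate bolus (`tk0 = 0`) is not part of the model and is rejected.
#' @param v Apparent volume of distribution (L), strictly positive.
#' @param cl Apparent clearance (L/h), strictly positive.
#'
#' @return An object of class `structural_params`: a list with elements
#'   `tk0`, `v`, `cl` and the derived `ke`.
#' @examples
#' structural_params(tk0 = 0.95, v = 32, cl = 16.13)
#' @export
structural_params <- function(tk0, v, cl) {
  for (nm in c("tk0", "v", "cl")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (val <= 0) {
      stop("`", nm, "` must be strictly positive (got ", val, ")", call. = FALSE)
    }
  }
  structure(list(tk0 = tk0, v = v, cl = cl, ke = cl / v),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("<structural_params> Tk0 = %.4g h, V = %.4g L, Cl = %.4g L/h (ke = %.4g /h)\n",
              x$tk0, x$v, x$cl, x$ke))
  invisible(x)
}

#' Dose schedule
#'
#' A sequence of oral dose events.  Times are hours since the first dose
#' and must be strictly increasing; an amount of 0 encodes a skipped dose.
#'
#' @param time Numeric vector of dose times (h), non-negative, strictly
#'   increasing.
#' @param amount Numeric vector of dose amounts (mg), non-negative,
#'   recycled to the length of `time`.
#'
#' @return A tibble of class `dose_schedule` with columns `time` and
#'   `amount`.
#' @examples
#' dose_schedule(0, 2000)
#' daily_doses(1000, n_days = 90)
#' @export
dose_schedule <- function(time, amount) {
  if (length(time) == 0L) stop("at least one dose event is required", call. = FALSE)
  amount <- rep_len(amount, length(time))
  if (!all(is.finite(time)) || !all(is.finite(amount))) {
    stop("dose times and amounts must be finite", call. = FALSE)
  }
  if (any(time < 0)) stop("dose times must be non-negative", call. = FALSE)
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("dose times must be strictly increasing", call. = FALSE)
  }
  if (any(amount < 0)) stop("dose amounts must be non-negative", call. = FALSE)
  out <- tibble::tibble(time = as.numeric(time), amount = as.numeric(amount))
  class(out) <- c("dose_schedule", class(out))
  out
}

#' @rdname dose_schedule
#' @param dose_mg Daily dose (mg).
#' @param n_days Number of once-daily doses.
#' @param interval_h Dosing interval (h), default 24.
#' @export
daily_doses <- function(dose_mg, n_days, interval_h = 24) {
  stopifnot(n_days >= 1)
  dose_schedule(time = (seq_len(n_days) - 1) * interval_h,
                amount = rep(dose_mg, n_days))
}

as_dose_schedule <- function(doses) {
  if (inherits(doses, "dose_schedule")) return(doses)
  if (is.data.frame(doses) && all(c("time", "amount") %in% names(doses))) {
    return(dose_schedule(doses$time, doses$amount))
  }
  stop("`doses` must be a dose_schedule() or a data frame with columns time, amount",
       call. = FALSE)
}

# Single-dose contribution, vectorised over u = t - t_dose.  D/(tk0*cl) is
# the plateau concentration reached if absorption ran to steady state.
single_dose_conc <- function(u, amount, tk0, v, cl) {
  ke <- cl / v
  a <- amount / (tk0 * cl)
  out <- a * (1 - exp(-ke * pmin(u, tk0))) * exp(-ke * pmax(u - tk0, 0))
  out[u < 0] <- 0
  out
}

#' Concentration-time function (closed form)
#'
#' Plasma concentration under multi-dose superposition of the
#' one-compartment, zero-order-absorption model.  For a dose of amount D
#' given at time td, with u = t - td:
#' 0 for u < 0; `(D/(tk0*cl)) * (1 - exp(-ke*u))` during absorption
#' (0 <= u <= tk0); and `(D/(tk0*cl)) * (1 - exp(-ke*tk0)) * exp(-ke*(u - tk0))`
#' afterwards.  The function is continuous in t and non-negative.
#'
#' @param params A [structural_params()] object.
#' @param doses A [dose_schedule()] (or data frame with `time`, `amount`).
#' @param t Numeric vector of query times (h), non-negative.
#'
#' @return Numeric vector of concentrations (mg/L), same length as `t`.
#' @examples
#' p <- structural_params(0.95, 32, 16.13)
#' concentration(p, dose_schedule(0, 2000), t = c(0, 0.95, 2))
#' @export
concentration <- function(params, doses, t) {
  stopifnot(inherits(params, "structural_params"))
  doses <- as_dose_schedule(doses)
  if (!all(is.finite(t))) stop("query times must be finite", call. = FALSE)
  if (any(t < 0)) stop("query times must be non-negative", call. = FALSE)
  out <- numeric(length(t))
  for (k in seq_len(nrow(doses))) {
    if (doses$amount[k] == 0) next
    out <- out + single_dose_conc(t - doses$time[k], doses$amount[k],
                                  params$tk0, params$v, params$cl)
  }
  out
}

#' Maximum concentration over a time window
#'
#' Searches the superposition profile over `window`.  Candidate times are
#' the dose times, the absorption-end times `td + tk0` and the window
#' edges; because the profile rises during each absorption interval and
#' decays between doses, the maximum lies on this candidate set whenever
#' absorption windows do not overlap.  A dense fallback grid (step
#' `grid_dt`) around the best candidate guards the general case.  For a
#' uniform once-daily schedule the geometric accumulation closed form is
#' used directly.
#'
#' @param params A [structural_params()] object.
#' @param doses A [dose_schedule()].
#' @param window Length-2 numeric, `c(t_start, t_end)` with
#'   `t_start < t_end`.
#' @param grid_dt Fallback grid resolution (h), default 0.01.
#'
#' @return A list with `cmax` (mg/L) and `tmax` (h).  If every dose amount
#'   is 0 the profile is identically zero and `(0, t_start)` is returned.
#' @examples
#' p <- structural_params(0.95, 32, 16.13)
#' cmax(p, dose_schedule(0, 2000), window = c(0, 24))
#' @export
cmax <- function(params, doses, window, grid_dt = 0.01) {
  stopifnot(inherits(params, "structural_params"))
  doses <- as_dose_schedule(doses)
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2]) {
    stop("`window` must be c(t_start, t_end) with t_start < t_end", call. = FALSE)
  }
  if (all(doses$amount == 0)) {
    return(list(cmax = 0, tmax = window[1]))
  }

  n <- nrow(doses)
  uniform <- n > 1L &&
    length(unique(doses$amount)) == 1L &&
    diff(range(diff(doses$time))) < 1e-9 &&
    params$tk0 < diff(doses$time)[1] &&
    abs(doses$time[1] - window[1]) < 1e-9 &&
    window[2] >= doses$time[n] + params$tk0
  if (uniform) {
    # accumulation: Cmax at the end of the last absorption interval
    tau <- diff(doses$time)[1]
    ke <- params$ke
    c1 <- single_dose_conc(params$tk0, doses$amount[1], params$tk0, params$v, params$cl)
    acc <- (1 - exp(-ke * n * tau)) / (1 - exp(-ke * tau))
    return(list(cmax = c1 * acc, tmax = doses$time[n] + params$tk0))
  }

  cand <- c(window, doses$time, doses$time + params$tk0)
  cand <- sort(unique(cand[cand >= window[1] & cand <= window[2]]))
  cc <- concentration(params, doses, cand)
  best <- which.max(cc)
  # local refinement grid around the best candidate
  lo <- max(window[1], cand[best] - 1)
  hi <- min(window[2], cand[best] + 1)
  grid <- seq(lo, hi, by = grid_dt)
  cg <- concentration(params, doses, grid)
  if (max(cg) > cc[best]) {
    list(cmax = max(cg), tmax = grid[which.max(cg)])
  } else {
    list(cmax = cc[best], tmax = cand[best])
  }
}

#' Numerical-integration oracle for the structural model
#'
#' Solves the two-state system (a depot delivering at constant rate
#' `D/tk0` for `tk0` hours per dose, and a central compartment with
#' first-order elimination `ke`) piecewise between input discontinuities
#' with `deSolve::lsoda` at tight tolerance.  Intended as an independent
#' check of [concentration()].
#'
#' @param params A [structural_params()] object.
#' @param doses A [dose_schedule()].
#' @param times Numeric vector of output times (h), non-negative.
#' @param rtol,atol Solver tolerances (default 1e-12).
#'
#' @return Numeric vector of concentrations (mg/L) at `times`.
#' @export
ode_oracle <- function(params, doses, times, rtol = 1e-12, atol = 1e-12) {
  stopifnot(inherits(params, "structural_params"))
  doses <- as_dose_schedule(doses)
  if (any(times < 0) || !all(is.finite(times))) {
    stop("output times must be finite and non-negative", call. = FALSE)
  }
  active <- doses[doses$amount > 0, , drop = FALSE]
  if (nrow(active) == 0L) return(numeric(length(times)))

  # breakpoints where the total input rate changes
  breaks <- sort(unique(c(0, active$time, active$time + params$tk0, times)))
  rate_at <- function(t) {
    sum(active$amount[active$time <= t + 1e-12 &
                        t < active$time + params$tk0 - 1e-12] / params$tk0)
  }
  deriv <- function(t, y, parms) list(parms$r / params$v - params$ke * y[1])

  conc <- numeric(length(breaks))
  for (i in seq_len(length(breaks) - 1L)) {
    seg <- c(breaks[i], breaks[i + 1L])
    if (seg[2] - seg[1] < 1e-13) { conc[i + 1L] <- conc[i]; next }
    r <- rate_at(mean(seg))
    sol <- deSolve::lsoda(c(C = conc[i]), seg, deriv, parms = list(r = r),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed on segment [", seg[1], ", ", seg[2], "]",
           call. = FALSE)
    }
    conc[i + 1L] <- sol[nrow(sol), "C"]
  }
  conc[match(times, breaks)]
}
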