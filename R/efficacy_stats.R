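# Contingency-table comparisons of regimens: odds ratios with Woolf
# confidence intervals, chi-square tests, number-needed-to-treat.
#
# Table layout (a, b, c, d): rows treated/control, columns event/no-event:
#   treated:  a events, b non-events
#   control:  c events, d non-events

check_table <- function(table) {
  if (is.matrix(table)) table <- as.vector(t(table))
  if (length(table) != 4L || any(!is.finite(table)) || any(table < 0) ||
      any(table != round(table))) {
    stop("`table` must be four non-negative integer counts (a, b, c, d)",
         call. = FALSE)
  }
  stats::setNames(as.numeric(table), c("a", "b", "c", "d"))
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a d) / (b c)`.  When any cell is zero and
#' `zero_cell_correction` is enabled, 0.5 is added to every cell
#' (Haldane-Anscombe) before computing both the OR and the interval.
#' The interval is `exp(log(OR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table Counts `c(a, b, c, d)` or a 2x2 matrix (rows
#'   treated/control, columns event/no-event).
#' @param zero_cell_correction Apply the +0.5 correction when needed
#'   (default TRUE).
#' @return A list with `or`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio(c(7, 8, 11, 2))
#' @export
odds_ratio <- function(table, zero_cell_correction = TRUE) {
  tb <- check_table(table)
  corrected <- FALSE
  if (any(tb == 0)) {
    if (!zero_cell_correction) {
      if (tb["b"] * tb["c"] == 0) {
        stop("zero cell makes the odds ratio undefined; enable ",
             "`zero_cell_correction`", call. = FALSE)
      }
    } else {
      tb <- tb + 0.5
      corrected <- TRUE
    }
  }
  or <- (tb["a"] * tb["d"]) / (tb["b"] * tb["c"])
  se <- sqrt(sum(1 / tb))
  list(or = unname(or),
       ci_low = unname(exp(log(or) - 1.96 * se)),
       ci_high = unname(exp(log(or) + 1.96 * se)),
       corrected = corrected)
}

#' Pearson chi-square test for a 2x2 table
#'
#' `X^2 = n (a d - b c)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.  The Yates
#' continuity correction subtracts n/2 from `|ad - bc|` when enabled.
#'
#' @param table Counts `c(a, b, c, d)` or a 2x2 matrix.
#' @param continuity_correction Apply the Yates correction (default
#'   FALSE).
#' @return A list with `chi_square`, `df` (= 1) and `p_value`.
#' @examples
#' chi_square(c(7, 8, 11, 2))
#' @export
chi_square <- function(table, continuity_correction = FALSE) {
  tb <- check_table(table)
  a <- tb["a"]; b <- tb["b"]; c <- tb["c"]; d <- tb["d"]
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) {
    # a degenerate margin carries no information
    return(list(chi_square = 0, df = 1L, p_value = 1))
  }
  num <- if (continuity_correction) max(abs(a * d - b * c) - n / 2, 0)^2
         else (a * d - b * c)^2
  x2 <- unname(n * num / denom)
  list(chi_square = x2, df = 1L,
       p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Number needed to treat
#'
#' `NNT = 1 / (p_control - p_treated)`, defined only when the treated
#' event probability is below the control one.
#'
#' @param p_control_event,p_treated_event Event probabilities in \[0, 1\].
#' @return A list with `nnt` (unrounded) and `nnt_ceiling` (rounded up).
#' @examples
#' nnt(0.9, 0.4)
#' @export
nnt <- function(p_control_event, p_treated_event) {
  stopifnot(p_control_event >= 0, p_control_event <= 1,
            p_treated_event >= 0, p_treated_event <= 1)
  if (p_control_event <= p_treated_event) {
    stop("NNT is undefined unless the treated event rate is below the ",
         "control rate", call. = FALSE)
  }
  v <- 1 / (p_control_event - p_treated_event)
  list(nnt = v, nnt_ceiling = ceiling(v))
}

#' Compare simulated regimens against an observed control (and each other)
#'
#' Simulated proportions are converted to event counts at a configurable
#' effective arm size (default: the observed evaluable arm sizes), then
#' every regimen is compared with the control arm, and every regimen pair
#' is compared, for both outcomes.  The effective n is always reported.
#'
#' @param sim_summary Tibble from [simulate_efficacy()] (needs columns
#'   `dose_mg`, `progression_pct`, `mortality_pct`), typically the
#'   full-adherence rows.
#' @param control Named list with `progression = c(events, n)` and
#'   `mortality = c(events, n)` observed control counts (defaults: 11/13
#'   and 12/13).
#' @param n_treated Effective treated arm size (default 13).
#' @param zero_cell_correction,continuity_correction Passed through.
#' @return A tibble with one row per comparison x outcome: `comparison`,
#'   `outcome`, `or`, `ci_low`, `ci_high`, `chi_square`, `df`, `p_value`,
#'   `nnt`, `n_treated`, `n_control`.
#' @export
compare_all <- function(sim_summary,
                        control = list(progression = c(11, 13),
                                       mortality = c(12, 13)),
                        n_treated = 13,
                        zero_cell_correction = TRUE,
                        continuity_correction = FALSE) {
  stopifnot(all(c("dose_mg", "progression_pct", "mortality_pct") %in%
                  names(sim_summary)))
  events_of <- function(pct, n) round(pct / 100 * n)
  rows <- list()
  add_row <- function(label, outcome, a, b, c, d, n_t, n_c) {
    orr <- odds_ratio(c(a, b, c, d), zero_cell_correction)
    x2 <- chi_square(c(a, b, c, d), continuity_correction)
    pc <- c / (c + d); pt <- a / (a + b)
    nn <- if (pc > pt) nnt(pc, pt)$nnt else NA_real_
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      comparison = label, outcome = outcome,
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      chi_square = x2$chi_square, df = x2$df, p_value = x2$p_value,
      nnt = nn, n_treated = n_t, n_control = n_c)
  }
  for (outcome in c("progression", "mortality")) {
    col <- if (outcome == "progression") "progression_pct" else "mortality_pct"
    ctrl <- control[[outcome]]
    for (i in seq_len(nrow(sim_summary))) {
      ev <- events_of(sim_summary[[col]][i], n_treated)
      add_row(paste0(sim_summary$dose_mg[i], "mg_vs_control"), outcome,
              ev, n_treated - ev, ctrl[1], ctrl[2] - ctrl[1],
              n_treated, ctrl[2])
    }
    if (nrow(sim_summary) > 1) {
      cmb <- utils::combn(seq_len(nrow(sim_summary)), 2)
      for (kk in seq_len(ncol(cmb))) {
        i <- cmb[1, kk]; j <- cmb[2, kk]
        ev_i <- events_of(sim_summary[[col]][i], n_treated)
        ev_j <- events_of(sim_summary[[col]][j], n_treated)
        add_row(paste0(sim_summary$dose_mg[j], "mg_vs_",
                       sim_summary$dose_mg[i], "mg"), outcome,
                ev_j, n_treated - ev_j, ev_i, n_treated - ev_i,
                n_treated, n_treated)
      }
    }
  }
  dplyr::bind_rows(rows)
}
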