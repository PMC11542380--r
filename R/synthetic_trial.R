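# Synthetic phase-2A-like trial generation and the tabular event format.
#
# The generated data stand in for the (non-public) clinical dataset: 3 arms
# (15/16/16 subjects), once-daily oral dosing, intensive PK sampling at 12
# time points on designated days.  Covariate values are drawn but carry no
# effect on the PK parameters.

DATASET_COLUMNS <- c("ID", "OCC", "TIME", "AMT", "DV", "EVID", "MDV",
                     "FLOOR", "SEX", "AGE", "WT", "HT")

#' Trial arm definition
#'
#' @param name Arm label.
#' @param n Number of subjects (>= 1).
#' @param doses_by_day Numeric vector, the once-daily dose (mg) for each
#'   study day; length is the treatment duration in days.  Use `numeric(0)`
#'   for an untreated control arm.
#' @param pk_days Integer vector of study days with intensive PK sampling
#'   (empty for arms without PK).
#' @return A list of class `trial_arm`.
#' @examples
#' trial_arm("group1", 15, rep(1000, 90), pk_days = 1)
#' @export
trial_arm <- function(name, n, doses_by_day, pk_days = integer()) {
  stopifnot(is.character(name), length(name) == 1L, n >= 1)
  if (length(pk_days) > 0) {
    stopifnot(all(pk_days >= 1), all(pk_days <= length(doses_by_day)))
  }
  structure(list(name = name, n = as.integer(n),
                 doses_by_day = as.numeric(doses_by_day),
                 pk_days = as.integer(pk_days)),
            class = "trial_arm")
}

#' Synthetic covariate generators
#'
#' Plausible synthetic demographics for an advanced-stage iCCA cohort
#' (the source cohort's demographics are not public): age ~ N(63, 8) y,
#' weight ~ N(58, 9) kg, height ~ N(160, 8) cm, sex ~ Bernoulli(0.5).
#' Covariates are generated but have no effect on the PK parameters.
#'
#' @param age_mean,age_sd,wt_mean,wt_sd,ht_mean,ht_sd,p_male Distribution
#'   parameters.
#' @return A list of class `covariate_generators`.
#' @export
covariate_generators <- function(age_mean = 63, age_sd = 8,
                                 wt_mean = 58, wt_sd = 9,
                                 ht_mean = 160, ht_sd = 8,
                                 p_male = 0.5) {
  structure(list(age_mean = age_mean, age_sd = age_sd, wt_mean = wt_mean,
                 wt_sd = wt_sd, ht_mean = ht_mean, ht_sd = ht_sd,
                 p_male = p_male),
            class = "covariate_generators")
}

#' Phase-2A-like trial design
#'
#' Defaults reproduce the study structure: group 1 receives 1,000 mg
#' once daily for 90 days with PK sampling on day 1 (n = 15); group 2 is
#' titrated 1,000 mg (days 1-14), 1,500 mg (days 15-28), 2,000 mg (days
#' 29-90) with PK sampling on days 14 and 28 (n = 16); group 3 is an
#' untreated control (n = 16, no PK).  Sampling times within a PK day are
#' 0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8 h post-dose.
#'
#' @param arms List of [trial_arm()] objects.
#' @param sampling_times Hours after the dose on a PK day; strictly
#'   increasing, first element 0.
#' @param covariates A [covariate_generators()] object.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(
    arms = list(
      trial_arm("group1", 15, rep(1000, 90), pk_days = 1),
      trial_arm("group2", 16, c(rep(1000, 14), rep(1500, 14), rep(2000, 62)),
                pk_days = c(14, 28)),
      trial_arm("group3", 16, numeric(0))),
    sampling_times = c(0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8),
    covariates = covariate_generators()) {
  stopifnot(length(arms) >= 1, all(vapply(arms, inherits, TRUE, "trial_arm")))
  if (sampling_times[1] != 0 || any(diff(sampling_times) <= 0)) {
    stop("sampling times must be strictly increasing with first element 0",
         call. = FALSE)
  }
  structure(list(arms = arms, sampling_times = sampling_times,
                 covariates = covariates),
            class = "trial_design")
}

#' Generate a synthetic trial dataset
#'
#' For every subject of every arm with PK sampling, and for each of that
#' arm's PK days: a fresh random-effect vector is drawn from the occasion's
#' population model, true concentrations after the day's dose are computed
#' with the structural model, and combined residual error is applied
#' (negative draws floored at 0 and flagged).  `TIME` is hours since the
#' occasion's dose.  Covariates are drawn once per subject and carry no PK
#' effect.
#'
#' @param design A [trial_design()].
#' @param models Named list mapping `"day<d>"` to a [population_model()]
#'   for every sampled day, e.g. the result of
#'   `list(day1 = ..., day14 = ..., day28 = ...)`.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A tibble in the event format (see [read_dataset()]), one dose
#'   row plus one row per observation for each subject-occasion.  The true
#'   simulated individual parameters are attached as attribute
#'   `"true_params"` (a tibble `ID`, `OCC`, `tk0`, `v`, `cl`) for
#'   recovery studies; they are not part of the file format.
#' @examples
#' mods <- al_model_presets()
#' d <- generate_trial(trial_design(),
#'                     models = list(day1 = mods$table1_day1,
#'                                   day14 = mods$table2_day14,
#'                                   day28 = mods$table3_day28),
#'                     seed = 1)
#' @export
generate_trial <- function(design, models, seed) {
  stopifnot(inherits(design, "trial_design"))
  withr::with_seed(seed, {
    rows <- list()
    truth <- list()
    id <- 0L
    for (arm in design$arms) {
      for (s in seq_len(arm$n)) {
        id <- id + 1L
        cg <- design$covariates
        sex <- stats::rbinom(1, 1, cg$p_male)
        age <- round(stats::rnorm(1, cg$age_mean, cg$age_sd), 1)
        wt <- round(stats::rnorm(1, cg$wt_mean, cg$wt_sd), 1)
        ht <- round(stats::rnorm(1, cg$ht_mean, cg$ht_sd), 1)
        for (day in arm$pk_days) {
          key <- paste0("day", day)
          pop <- models[[key]]
          if (is.null(pop)) {
            stop("no population model supplied for occasion '", key, "'",
                 call. = FALSE)
          }
          pat <- sample_patients(pop, 1)
          pars <- structural_params(pat$tk0, pat$v, pat$cl)
          truth[[length(truth) + 1L]] <- tibble::tibble(
            ID = id, OCC = day, tk0 = pat$tk0, v = pat$v, cl = pat$cl)
          amt <- arm$doses_by_day[day]
          true_c <- concentration(pars, dose_schedule(0, amt),
                                  design$sampling_times)
          obs <- residual_observe(true_c, pop)
          sub <- tibble::tibble(
            ID = id, OCC = day,
            TIME = c(0, design$sampling_times),
            AMT = c(amt, rep(NA_real_, length(design$sampling_times))),
            DV = c(NA_real_, obs$conc),
            EVID = c(1L, rep(0L, length(design$sampling_times))),
            MDV = c(1L, rep(0L, length(design$sampling_times))),
            FLOOR = c(0L, as.integer(obs$below_floor)),
            SEX = sex, AGE = age, WT = wt, HT = ht)
          rows[[length(rows) + 1L]] <- sub
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "true_params") <- dplyr::bind_rows(truth)
    out
  })
}

#' Write / read a trial dataset
#'
#' Comma-separated text with header, NONMEM-dialect event semantics:
#' `EVID` 1 marks a dose row (`AMT` in mg, `MDV` 1, `DV` missing), `EVID`
#' 0 an observation row (`DV` in mg/L, `TIME` in h since the occasion's
#' dose).  `OCC` is the study day of the occasion, `FLOOR` flags
#' observations floored at 0 after a negative residual draw, and `SEX`
#' (1 = male), `AGE` (y), `WT` (kg), `HT` (cm) are covariates.  Missing
#' values are written as ".".  Reading validates the file strictly and
#' reports offending data lines by number.
#'
#' @param dataset A dataset tibble (from [generate_trial()] or
#'   [read_dataset()]).
#' @param path File path.
#' @return `read_dataset()` returns the validated tibble;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  missing_cols <- setdiff(DATASET_COLUMNS, names(dataset))
  if (length(missing_cols)) {
    stop("dataset lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(dataset[DATASET_COLUMNS], path, na = ".")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  unknown <- setdiff(names(raw), DATASET_COLUMNS)
  if (length(unknown)) {
    stop("unknown dataset columns: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing dataset columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  bad_evid <- which(!raw$EVID %in% c(0, 1))
  if (length(bad_evid)) {
    stop("EVID must be 0 or 1 (line ", line_no[bad_evid[1]], ")", call. = FALSE)
  }
  amb <- which(raw$EVID == 1 & !is.na(raw$DV))
  if (length(amb)) {
    stop("dose row carries an observation value: dose/observation ambiguity (line ",
         line_no[amb[1]], ")", call. = FALSE)
  }
  neg <- which(raw$EVID == 0 & raw$DV < 0)
  if (length(neg)) {
    stop("negative concentration (line ", line_no[neg[1]], ")", call. = FALSE)
  }
  no_dv <- which(raw$EVID == 0 & raw$MDV == 0 & is.na(raw$DV))
  if (length(no_dv)) {
    stop("observation row with MDV = 0 but missing DV (line ",
         line_no[no_dv[1]], ")", call. = FALSE)
  }

  for (key in split(seq_len(nrow(raw)), paste(raw$ID, raw$OCC))) {
    sub <- raw[key, ]
    if (!any(sub$EVID == 1)) {
      stop("subject ", sub$ID[1], " occasion ", sub$OCC[1],
           " has no dose row", call. = FALSE)
    }
    ot <- sub$TIME[sub$EVID == 0]
    if (length(ot) > 1 && any(diff(ot) <= 0)) {
      bad <- key[sub$EVID == 0][which(diff(ot) <= 0)[1] + 1L]
      stop("non-monotone observation times for subject ", sub$ID[1],
           " occasion ", sub$OCC[1], " (line ", line_no[bad], ")",
           call. = FALSE)
    }
    first_dose <- min(sub$TIME[sub$EVID == 1])
    pre <- sub$EVID == 0 & sub$TIME < first_dose & !is.na(sub$DV) & sub$DV > 0
    if (any(pre)) {
      warning("pre-dose observation with positive concentration for subject ",
              sub$ID[1], " occasion ", sub$OCC[1], " (line ",
              line_no[key[pre][1]], ")", call. = FALSE)
    }
  }

  raw$ID <- as.integer(raw$ID); raw$OCC <- as.integer(raw$OCC)
  raw$EVID <- as.integer(raw$EVID); raw$MDV <- as.integer(raw$MDV)
  raw$FLOOR <- as.integer(raw$FLOOR)
  raw
}

#' Extract one occasion from a dataset
#'
#' Estimation is performed per occasion (the occasions were fitted as
#' separate models); this selects the rows of a single study day.
#'
#' @param dataset A dataset tibble.
#' @param day Study day (matches the `OCC` column).
#' @return The subset tibble.
#' @export
occasion_data <- function(dataset, day) {
  out <- dataset[dataset$OCC == day, , drop = FALSE]
  if (nrow(out) == 0L) stop("no rows for occasion day ", day, call. = FALSE)
  out
}
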