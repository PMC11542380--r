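# Contingency statistics against first-principles enumeration.

# Independent oracles: chi-square via observed-vs-expected cell sums,
# odds ratio via direct cross-products on (optionally corrected) cells.
oracle_chi2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) return(0)
  sum((o - e)^2 / e)
}
oracle_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a / b) / (c / d)
}

test_that("the frozen hand-oracle values for the observed table hold", {
  expect_equal(odds_ratio(c(7, 8, 11, 2))$or, 14 / 88, tolerance = 1e-12)
  expect_equal(chi_square(c(7, 8, 11, 2))$chi_square, 4.368319,
               tolerance = 1e-6)
  expect_equal(chi_square(c(7, 8, 11, 2))$p_value,
               pchisq(4.368319, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("odds ratio and chi-square match brute force on all small tables", {
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    tab <- c(a, b, c, d)
    x2 <- chi_square(tab)$chi_square
    expect_equal(x2, oracle_chi2(a, b, c, d), tolerance = 1e-10)
    if (sum(tab) > 0) {
      or <- odds_ratio(tab)$or
      expect_equal(or, oracle_or(a, b, c, d), tolerance = 1e-10)
    }
  }
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(19)
  for (i in 1:50) {
    tab <- rpois(4, 12) + 1
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(chi_square(tab)$chi_square,
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-9)
    expect_equal(chi_square(tab, continuity_correction = TRUE)$chi_square,
                 unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
                 tolerance = 1e-9)
  }
})

test_that("symmetries: equal proportions, row swap, full swap", {
  expect_equal(odds_ratio(c(5, 5, 5, 5))$or, 1)
  expect_equal(odds_ratio(c(7, 8, 11, 2))$or,
               1 / odds_ratio(c(11, 2, 7, 8))$or, tolerance = 1e-12)
  expect_equal(chi_square(c(10, 10, 10, 10))$chi_square, 0)
  expect_equal(chi_square(c(10, 10, 10, 10))$p_value, 1)
  expect_equal(chi_square(c(7, 8, 11, 2))$chi_square,
               chi_square(c(2, 11, 8, 7))$chi_square, tolerance = 1e-12)
})

test_that("zero cells require the Haldane correction or fail loudly", {
  expect_error(odds_ratio(c(5, 0, 3, 4), zero_cell_correction = FALSE),
               "zero cell")
  res <- odds_ratio(c(5, 0, 3, 4))
  expect_true(res$corrected)
  expect_equal(res$or, (5.5 * 4.5) / (0.5 * 3.5), tolerance = 1e-12)
  expect_error(odds_ratio(c(1.5, 2, 3, 4)), "integer")
  expect_error(odds_ratio(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Woolf CI excluding 1 tracks p < 0.05 up to boundary noise", {
  set.seed(31)
  mism <- 0
  for (i in 1:1000) {
    tab <- rpois(4, 8) + 1
    orr <- odds_ratio(tab)
    x2 <- chi_square(tab)
    excl <- orr$ci_low > 1 || orr$ci_high < 1
    sig <- x2$p_value < 0.05
    if (excl != sig) {
      mism <- mism + 1
      expect_lt(abs(x2$p_value - 0.05), 0.01)  # only boundary cases disagree
    }
  }
  expect_lt(mism, 100)
})

test_that("NNT follows the risk difference and rejects undefined input", {
  expect_equal(nnt(0.9, 0.4)$nnt, 2)
  expect_identical(nnt(0.9, 0.4)$nnt_ceiling, 2)
  expect_equal(nnt(0.8461, 0.27)$nnt, 1 / (0.8461 - 0.27), tolerance = 1e-12)
  expect_error(nnt(0.5, 0.5), "undefined")
  expect_error(nnt(0.3, 0.5), "undefined")
})

test_that("compare_all reports every regimen and pair with the n used", {
  sim <- tibble::tibble(dose_mg = c(2000, 2500, 3000),
                        progression_pct = c(55, 27, 12),
                        mortality_pct = c(29, 12, 3))
  res <- compare_all(sim)
  # 3 vs control + 3 pairs, for each of 2 outcomes
  expect_identical(nrow(res), 12L)
  expect_true(all(res$n_treated == 13))
  # identity comparison when treated equals control
  same <- compare_all(tibble::tibble(dose_mg = 1, progression_pct = 100 * 11 / 13,
                                     mortality_pct = 100 * 12 / 13))
  vs <- same[grepl("control", same$comparison), ]
  expect_true(all(abs(vs$or - 1) < 1e-9))
  # OR against control decreases with dose for both outcomes
  for (oc in c("progression", "mortality")) {
    ors <- res$or[res$outcome == oc & grepl("control", res$comparison)]
    expect_true(all(diff(ors) < 0))
  }
})
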