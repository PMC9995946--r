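line_data <- function(n = 20, slope = 2, intercept = 1, cohort = "CN",
                      ages = NULL) {
  ages <- ages %||% seq(60, 85, length.out = n)
  tibble::tibble(subject_id = sprintf("L%02d", seq_along(ages)),
                 cohort = factor(cohort, levels = cohort_levels()),
                 age = ages,
                 DSST = intercept + slope * ages)
}

test_that("an exact line is recovered with a vanishing slope SE", {
  suppressWarnings(fit <- fit_trend(line_data(), "CN", "DSST"))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_lt(abs(fit$slope_se), 1e-10)
})

test_that("a two-point trend is exact with an undefined SE", {
  expect_warning(fit <- fit_trend(line_data(n = 2, ages = c(60, 80)),
                                  "CN", "DSST"), "undefined")
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_true(is.na(fit$slope_se))
})

test_that("degenerate trend inputs raise errors", {
  expect_error(fit_trend(line_data(n = 1, ages = 70), "CN", "DSST"),
               "at least 2")
  expect_error(fit_trend(line_data(ages = rep(70, 5)), "CN", "DSST"),
               "singular")
  expect_error(fit_trend(line_data(), "CN", "nope"), "nope")
})

test_that("the interaction equals the slope difference of separate fits", {
  d <- dplyr::bind_rows(
    line_data(cohort = "CN"),
    line_data(slope = 0.5, intercept = 40, cohort = "MCI"))
  set.seed(60)
  d$DSST <- d$DSST + rnorm(nrow(d), 0, 3)
  cmp <- compare_slopes(d, "CN", "MCI", "DSST")
  f_cn <- fit_trend(d, "CN", "DSST")
  f_mci <- fit_trend(d, "MCI", "DSST")
  expect_equal(cmp$estimate, f_mci$slope - f_cn$slope, tolerance = 1e-8)
  expect_equal(cmp$ci_lo, cmp$estimate - 1.96 * cmp$sd)
  # swapping the cohorts flips the sign exactly
  rev <- compare_slopes(d, "MCI", "CN", "DSST")
  expect_equal(rev$estimate, -cmp$estimate, tolerance = 1e-12)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
})

test_that("trendline intersection solves the two-line closed form", {
  mk <- function(intercept, slope) {
    structure(list(cohort = "CN", outcome = "DSST", slope = slope,
                   intercept = intercept, slope_se = 0.1, ci_lo = NA,
                   ci_hi = NA, n = 10, age_center = 0, fit = NULL),
              class = "sfa_trend")
  }
  a <- mk(90, -0.6)
  b <- mk(60, -0.3)
  expect_equal(convergence_age(a, b), 100)
  expect_equal(convergence_age(b, a), 100)     # symmetric
  expect_true(is.na(convergence_age(a, mk(10, -0.6))))  # parallel
  b$outcome <- "TMT_B"
  expect_error(convergence_age(a, b), "different outcomes")
})

test_that("synthetic CN DSST recovers its generating slope", {
  d <- sim_data(n = 5000, seed = 61, noise = 0.3)
  # only CN rows are needed; ignore the other cohorts
  fit <- fit_trend(d, "CN", "DSST")
  expect_lt(abs(fit$slope - (-0.616)), 3 * fit$slope_se)
})

test_that("slope-comparison null calibration holds under identical generators", {
  hits <- sapply(1:60, function(s) {
    d <- sim_data(n = 60, seed = 1200 + s, null = TRUE)
    cmp <- compare_slopes(d, "CN", "MCI", "DSST")
    cmp$p_value > 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("three-group tests match hand-computed statistics", {
  d <- tibble::tibble(
    subject_id = sprintf("K%02d", 1:9),
    cohort = factor(rep(cohort_levels(), each = 3),
                    levels = cohort_levels()),
    score = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  gc <- group_comparison(d, "score", "continuous")
  expect_equal(gc$statistic, 7.2, tolerance = 1e-12)
  expect_equal(gc$df, 2)
})

test_that("identical samples and identical proportions are null results", {
  d <- tibble::tibble(
    subject_id = sprintf("N%02d", 1:15),
    cohort = factor(rep(cohort_levels(), each = 5),
                    levels = cohort_levels()),
    score = rep(c(1, 2, 3, 4, 5), times = 3),
    grp = rep(c("a", "a", "a", "b", "b"), times = 3))
  cont <- group_comparison(d, "score", "continuous")
  expect_lt(cont$statistic, 1e-10)
  expect_equal(cont$p_value, 1)
  cat_ <- suppressWarnings(group_comparison(d, "grp", "categorical"))
  expect_lt(cat_$statistic, 1e-10)
})

test_that("a missing cohort is a test error", {
  d <- tibble::tibble(subject_id = c("a", "b"),
                      cohort = factor(c("CN", "MCI"),
                                      levels = cohort_levels()),
                      score = c(1, 2))
  expect_error(group_comparison(d, "score", "continuous"), "Dementia")
})
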