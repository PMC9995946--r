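# Age-trend analytics: per-cohort linear trendlines, slope-interaction
# comparisons between cohorts, trendline convergence ages, and three-group
# comparison tests.

#' Fit a linear age trendline within one cohort
#'
#' Ordinary least squares of an outcome (a test score, or any numeric
#' column such as `GM_TIV`) on age.  Age is centred at the pooled mean age
#' of `data` for numerical stability; the reported intercept is back-mapped
#' to age 0 so trendlines from the same dataset can be intersected directly.
#'
#' @param data Subject-level tibble.
#' @param cohort Cohort to fit within.
#' @param outcome Name of a numeric column.
#' @return An object of class `sfa_trend` with `slope` (units/year),
#'   `intercept` (units at age 0), `slope_se`, `ci_lo`, `ci_hi`, `n`, and
#'   the underlying `lm` fit.  A two-point fit is perfect with an undefined
#'   SE (`NA`, with a warning).
#' @export
fit_trend <- function(data, cohort, outcome) {
  assert_cohort(cohort)
  if (!outcome %in% names(data)) {
    stop("no column `", outcome, "` in `data`", call. = FALSE)
  }
  center <- mean(data$age, na.rm = TRUE)
  d <- data[data$cohort == cohort & !is.na(data[[outcome]]) &
              !is.na(data$age), , drop = FALSE]
  if (nrow(d) < 2) {
    stop("need at least 2 ", cohort, " records with `age` and `", outcome,
         "`", call. = FALSE)
  }
  if (sd(d$age) == 0) {
    stop("age is constant in the ", cohort, " subset; trend is singular",
         call. = FALSE)
  }
  if (nrow(d) == 2) {
    warning("two-point trend: fit is exact but the slope SE is undefined",
            call. = FALSE)
  }
  ac <- d$age - center
  fit <- lm(d[[outcome]] ~ ac)
  cf <- summary(fit)$coefficients
  slope <- cf["ac", "Estimate"]
  se <- if (nrow(d) > 2) cf["ac", "Std. Error"] else NA_real_
  structure(list(
    cohort = cohort, outcome = outcome,
    slope = unname(slope),
    intercept = unname(cf["(Intercept)", "Estimate"] - slope * center),
    slope_se = unname(se),
    ci_lo = unname(slope - 1.96 * se), ci_hi = unname(slope + 1.96 * se),
    n = nrow(d), age_center = center, fit = fit
  ), class = "sfa_trend")
}

#' @export
print.sfa_trend <- function(x, ...) {
  cat(sprintf("<sfa_trend> %s ~ age in %s: slope %.4f +/- %.4f /y (n = %d)\n",
              x$outcome, x$cohort, x$slope,
              if (is.na(x$slope_se)) NA else x$slope_se, x$n))
  invisible(x)
}

#' @describeIn fit_trend One-row tibble of the trend estimates.
#' @param x,... Method arguments.
#' @method tidy sfa_trend
#' @export
tidy.sfa_trend <- function(x, ...) {
  tibble::tibble(cohort = x$cohort, outcome = x$outcome, slope = x$slope,
                 intercept = x$intercept, slope_se = x$slope_se,
                 ci_lo = x$ci_lo, ci_hi = x$ci_hi, n = x$n)
}

#' Compare age slopes between two cohorts
#'
#' Fits `outcome ~ age * cohort` by OLS on the two-cohort subset with the
#' reference cohort as baseline and reports the age-by-group interaction
#' coefficient: the difference between the comparison and reference cohort
#' slopes, with its standard error, 95% CI and p-value.
#'
#' @inheritParams fit_trend
#' @param ref_cohort,cmp_cohort The two cohorts; the estimate is
#'   `slope(cmp) - slope(ref)`.
#' @return A one-row tibble: `reference`, `comparison`, `outcome`,
#'   `estimate` (units/year), `sd` (its standard error), `ci_lo`, `ci_hi`,
#'   `p_value`, `n`.
#' @export
compare_slopes <- function(data, ref_cohort, cmp_cohort, outcome) {
  assert_cohort(ref_cohort)
  assert_cohort(cmp_cohort)
  if (identical(ref_cohort, cmp_cohort)) {
    stop("`ref_cohort` and `cmp_cohort` must differ", call. = FALSE)
  }
  d <- data[as.character(data$cohort) %in% c(ref_cohort, cmp_cohort) &
              !is.na(data[[outcome]]) & !is.na(data$age), , drop = FALSE]
  n_by <- table(as.character(d$cohort))
  if (any(!c(ref_cohort, cmp_cohort) %in% names(n_by)) ||
      any(n_by[c(ref_cohort, cmp_cohort)] < 3)) {
    stop("need at least 3 records in each of ", ref_cohort, " and ",
         cmp_cohort, call. = FALSE)
  }
  grp <- factor(as.character(d$cohort), levels = c(ref_cohort, cmp_cohort))
  ac <- d$age - mean(d$age)
  fit <- lm(d[[outcome]] ~ ac * grp)
  cf <- summary(fit)$coefficients
  term <- paste0("ac:grp", cmp_cohort)
  if (!term %in% rownames(cf)) {
    stop("interaction term could not be estimated (singular design)",
         call. = FALSE)
  }
  est <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  tibble::tibble(
    reference = ref_cohort, comparison = cmp_cohort, outcome = outcome,
    estimate = unname(est), sd = unname(se),
    ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
    p_value = unname(cf[term, "Pr(>|t|)"]), n = nrow(d)
  )
}

#' Intersection age of two cohort trendlines
#'
#' Solves `intercept_a + slope_a * age = intercept_b + slope_b * age`.
#' Cohort trendlines of processing-speed tests (DSST, TMT-B) intersect at
#' roughly 100 years of age — the package's synthetic generator is
#' calibrated to that convergence.
#'
#' @param fit_a,fit_b `sfa_trend` objects for the same outcome.
#' @return Age in years, or `NA` when the slopes are equal within `1e-9`
#'   (parallel lines).  Symmetric in its arguments.
#' @export
convergence_age <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "sfa_trend"), inherits(fit_b, "sfa_trend"))
  if (!identical(fit_a$outcome, fit_b$outcome)) {
    stop("trend fits are for different outcomes (", fit_a$outcome, " vs ",
         fit_b$outcome, ")", call. = FALSE)
  }
  ds <- fit_a$slope - fit_b$slope
  if (abs(ds) <= 1e-9) return(NA_real_)
  (fit_b$intercept - fit_a$intercept) / ds
}

#' Three-group comparison test
#'
#' Kruskal-Wallis rank test for continuous variables and the chi-square
#' test on the cohort-by-category contingency table for categorical ones,
#' across the three diagnostic cohorts.
#'
#' @param data Subject-level tibble with all three cohorts present.
#' @param variable Column name to compare.
#' @param kind `"continuous"` or `"categorical"`.
#' @return A one-row tibble: `variable`, `kind`, `statistic`, `df`,
#'   `p_value`, `method`.
#' @export
group_comparison <- function(data, variable,
                             kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!variable %in% names(data)) {
    stop("no column `", variable, "` in `data`", call. = FALSE)
  }
  present <- cohort_levels() %in% unique(as.character(data$cohort))
  if (!all(present)) {
    stop("cohort(s) missing from `data`: ",
         paste(cohort_levels()[!present], collapse = ", "), call. = FALSE)
  }
  g <- factor(as.character(data$cohort), levels = cohort_levels())
  if (kind == "continuous") {
    ht <- kruskal.test(data[[variable]], g)
  } else {
    ht <- chisq.test(table(g, data[[variable]]))
  }
  tibble::tibble(variable = variable, kind = kind,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value, method = ht$method)
}
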