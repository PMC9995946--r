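# Resampled evaluation of the SFA regressions: MAE and MAE/range (%), the
# metrics that make prediction errors comparable across test scales.

#' Empirical score range of a test
#'
#' Maximum minus minimum observed score over the *pooled* dataset (all
#' cohorts).  Observed ranges are much narrower than the nominal scales
#' (e.g. MMSE spans about 18 of its 30 points in an elderly clinical
#' population), and it is the empirical range that makes MAE/range
#' percentages consistent across cohorts.
#'
#' @param data Subject-level tibble.
#' @param test One of `test_scales()$name`.
#' @return Numeric scalar (score units).  A degenerate single-valued score
#'   returns 0 with a warning.
#' @export
empirical_range <- function(data, test) {
  assert_test(test)
  x <- data[[test]]
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop("need at least 2 non-missing ", test, " scores", call. = FALSE)
  }
  r <- max(x) - min(x)
  if (r == 0) {
    warning(test, " has a single distinct value; MAE/range is undefined",
            call. = FALSE)
  }
  r
}

#' Express an MAE as percent of a score range
#'
#' @param mae Mean absolute error (score units).
#' @param range Score range (score units), must be positive.
#' @return `100 * mae / range`.
#' @export
mae_to_range_pct <- function(mae, range) {
  if (!is.numeric(range) || any(range <= 0)) {
    stop("`range` must be positive", call. = FALSE)
  }
  100 * mae / range
}

#' Cross-validated evaluation of one SFA model configuration
#'
#' Repeated k-fold cross-validation with folds grouped by `subject_id` (all
#' visits of a subject stay in one fold, so longitudinal records cannot leak
#' between train and test).  Reports the mean held-out MAE, its standard
#' error across folds, a 95% CI, and MAE as a percentage of the test's
#' empirical pooled range.
#'
#' @inheritParams fit_sfa_model
#' @param k_folds,n_repeats Cross-validation protocol (default 10 x 10).
#' @param seed Integer; fold assignment is deterministic given it.
#' @param range `"empirical"` (pooled max - min of `data`) or `"nominal"`
#'   (the scale's full span from [test_scales()]).
#' @return A one-row tibble of class `sfa_evaluation`: `cohort`, `test`,
#'   `feature_set`, `mae_mean`, `mae_se`, `ci_lo`, `ci_hi`, `mae_range_pct`,
#'   `range_used`, `n_splits`, `n`.  Per-fold MAEs and fold membership are
#'   attached as attributes `fold_maes` and `cv_detail`.
#' @export
evaluate_model_cv <- function(data, cohort, test, feature_set = "VBM",
                              alpha = 0.5, k_folds = 10, n_repeats = 10,
                              seed = 1L, range = c("empirical", "nominal")) {
  assert_cohort(cohort)
  assert_test(test)
  range <- match.arg(range)
  d <- data[data$cohort == cohort & !is.na(data[[test]]), , drop = FALSE]
  subjects <- unique(as.character(d$subject_id))
  if (length(subjects) < k_folds) {
    stop("fewer subjects (", length(subjects), ") than folds (", k_folds,
         ")", call. = FALSE)
  }
  set.seed(seed)
  fold_maes <- numeric(0)
  detail <- list()
  for (r in seq_len(n_repeats)) {
    shuffled <- sample(subjects)
    fold_of <- setNames(rep(seq_len(k_folds), length.out = length(subjects)),
                        shuffled)
    for (k in seq_len(k_folds)) {
      test_subj <- names(fold_of)[fold_of == k]
      tr <- d[!(as.character(d$subject_id) %in% test_subj), , drop = FALSE]
      te <- d[as.character(d$subject_id) %in% test_subj, , drop = FALSE]
      fit <- fit_sfa_model(tr, cohort, test, feature_set, alpha)
      pred <- predict_score(fit, te)
      fold_maes <- c(fold_maes, mean(abs(pred - te[[test]])))
      detail[[length(detail) + 1L]] <-
        tibble::tibble(rep = r, fold = k, subject_id = test_subj)
    }
  }
  n_splits <- length(fold_maes)
  mae_mean <- mean(fold_maes)
  mae_se <- sd(fold_maes) / sqrt(n_splits)
  range_used <- if (range == "empirical") {
    empirical_range(data, test)
  } else {
    diff(scale_bounds(test))
  }
  out <- tibble::tibble(
    cohort = cohort, test = test, feature_set = feature_set,
    mae_mean = mae_mean, mae_se = mae_se,
    ci_lo = mae_mean - 1.96 * mae_se, ci_hi = mae_mean + 1.96 * mae_se,
    mae_range_pct = if (range_used > 0) {
      mae_to_range_pct(mae_mean, range_used)
    } else {
      NA_real_
    },
    range_used = range_used, n_splits = n_splits, n = nrow(d)
  )
  attr(out, "fold_maes") <- fold_maes
  attr(out, "cv_detail") <- dplyr::bind_rows(detail)
  class(out) <- c("sfa_evaluation", class(out))
  out
}

#' Evaluate a grid of model configurations
#'
#' Convenience wrapper running [evaluate_model_cv()] over every combination
#' of cohort, test and feature set — the layout of the package's
#' cohort-by-feature-set performance tables.
#'
#' @inheritParams evaluate_model_cv
#' @param cohorts,tests,feature_sets Character vectors of configurations.
#' @return A tibble with one [evaluate_model_cv()] row per combination.
#' @export
evaluation_table <- function(data, cohorts = cohort_levels(),
                             tests = test_scales()$name,
                             feature_sets = "VBM", alpha = 0.5,
                             k_folds = 10, n_repeats = 10, seed = 1L,
                             range = "empirical") {
  grid <- tidyr::expand_grid(cohort = cohorts, test = tests,
                             feature_set = feature_sets)
  purrr::pmap(grid, function(cohort, test, feature_set) {
    evaluate_model_cv(data, cohort, test, feature_set, alpha = alpha,
                      k_folds = k_folds, n_repeats = n_repeats, seed = seed,
                      range = range)
  }) |>
    dplyr::bind_rows()
}
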