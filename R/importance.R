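# Impurity-based feature-importance rankings aggregated over four tree
# ensembles, and region-score correlation tables.

# AdaBoost.R2 (Drucker 1997) on rpart base learners; we only need the
# weighted impurity importances, not the predictor itself.
adaboost_r2_importance <- function(X, y, n_rounds = 50, maxdepth = 3) {
  n <- nrow(X)
  df <- data.frame(y = y, X, check.names = FALSE)
  w <- rep(1 / n, n)
  imp <- setNames(numeric(ncol(X)), colnames(X))
  for (m in seq_len(n_rounds)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 1e-3, xval = 0,
                                                       maxsurrogate = 0,
                                                       usesurrogate = 0))
    err <- abs(predict(fit, df) - y)
    d_max <- max(err)
    vi <- fit$variable.importance
    if (d_max == 0) {            # perfect learner: take it and stop
      if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + vi
      break
    }
    loss <- err / d_max
    lbar <- sum(w * loss)
    if (lbar >= 0.5) break
    beta <- lbar / (1 - lbar)
    if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + log(1 / beta) * vi
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  imp
}

normalize_importance <- function(v, feats) {
  out <- setNames(numeric(length(feats)), feats)
  out[names(v)] <- pmax(v, 0)
  s <- sum(out)
  if (s > 0) out / s else out + 1 / length(out)
}

#' Rank structural predictors by ensemble feature importance
#'
#' Fits four tree ensembles — Random Forest and Extra Trees (via
#' \pkg{ranger}), gradient boosting (via \pkg{xgboost}), and AdaBoost.R2 on
#' \pkg{rpart} learners — regressing one cohort's test score on its
#' morphometric features, extracts each ensemble's impurity/gain feature
#' importances, normalises each to sum to one, and averages them.  Feature
#' columns are canonicalised (sorted by name) before fitting so the ranking
#' does not depend on column order.
#'
#' @inheritParams fit_sfa_model
#' @param seed Integer seed; the ensembles are fitted single-threaded so the
#'   ranking is deterministic given it.
#' @param num_trees Trees per forest (Random Forest, Extra Trees).
#' @param xgb_rounds,adaboost_rounds Boosting rounds.
#' @return A tibble of class `sfa_ranking`, sorted by decreasing aggregated
#'   `importance`, with the per-ensemble normalised importances as columns
#'   `random_forest`, `extra_trees`, `gradient_boosting`, `adaboost`.
#' @export
rank_features <- function(data, cohort, test, feature_set = "VBM+SBM",
                          seed = 1L, num_trees = 500, xgb_rounds = 200,
                          adaboost_rounds = 50) {
  assert_cohort(cohort)
  assert_test(test)
  feats <- sort(feature_columns(data, feature_set))
  d <- data[data$cohort == cohort & !is.na(data[[test]]), , drop = FALSE]
  d <- d[complete.cases(d[, feats]), , drop = FALSE]
  if (nrow(d) < 20) {
    warning("ranking on fewer than 20 records is unstable (n = ", nrow(d),
            ")", call. = FALSE)
  }
  y <- d[[test]]
  if (length(unique(y)) < 2) {
    stop("cannot rank features against a constant ", test, " score",
         call. = FALSE)
  }
  X <- as.matrix(d[, feats])
  df <- data.frame(y = y, X, check.names = FALSE)

  # regression forests consider every feature at each split (the convention
  # of the ML stack this pipeline mirrors); randomness stays in the
  # bootstrap (RF) and in the random cut points (Extra Trees)
  rf <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                       importance = "impurity", mtry = ncol(X),
                       seed = seed, num.threads = 1)
  et <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                       importance = "impurity", splitrule = "extratrees",
                       num.random.splits = 1, mtry = ncol(X),
                       replace = FALSE, sample.fraction = 1,
                       seed = seed + 1L, num.threads = 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  gb <- xgboost::xgb.train(
    params = list(max_depth = 3, eta = 0.1, nthread = 1, seed = seed),
    data = dtrain, nrounds = xgb_rounds, verbose = 0)
  gbi <- xgboost::xgb.importance(model = gb)
  set.seed(seed + 2L)
  ada <- adaboost_r2_importance(X, y, n_rounds = adaboost_rounds)

  per <- list(
    random_forest = normalize_importance(rf$variable.importance, feats),
    extra_trees = normalize_importance(et$variable.importance, feats),
    gradient_boosting = normalize_importance(
      setNames(gbi$Gain, gbi$Feature), feats),
    adaboost = normalize_importance(ada, feats)
  )
  agg <- Reduce(`+`, per) / length(per)
  out <- tibble::tibble(feature = feats, importance = unname(agg)) |>
    dplyr::bind_cols(tibble::as_tibble(lapply(per, unname))) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  attr(out, "cohort") <- cohort
  attr(out, "test") <- test
  attr(out, "ensembles_used") <- names(per)
  class(out) <- c("sfa_ranking", class(out))
  out
}

#' Correlate cortical parcellation volumes with a test score
#'
#' Pearson correlation (with two-sided p-value) between each cortical
#' regional volume (`vbm_ctx_*` columns) and one cohort's test score — the
#' tabular counterpart of significance-thresholded cortical correlation
#' maps.
#'
#' @inheritParams fit_sfa_model
#' @param alpha_level Significance threshold.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment across regions.
#' @return A tibble with `region`, `r`, `p`, `significant`.  Zero-variance
#'   regions get `NA` correlations and are never flagged significant.
#' @export
correlate_regions <- function(data, cohort, test, alpha_level = 0.05,
                              adjust = c("none", "BH")) {
  assert_cohort(cohort)
  assert_test(test)
  adjust <- match.arg(adjust)
  regions <- names(data)[startsWith(names(data), "vbm_ctx_")]
  if (length(regions) == 0) {
    stop("no cortical parcellation (`vbm_ctx_*`) columns in `data`",
         call. = FALSE)
  }
  d <- data[data$cohort == cohort & !is.na(data[[test]]), , drop = FALSE]
  y <- d[[test]]
  res <- purrr::map(regions, function(rg) {
    x <- d[[rg]]
    ok <- !is.na(x)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(region = rg, r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(region = rg, r = unname(ct$estimate), p = ct$p.value)
  }) |>
    dplyr::bind_rows()
  p_used <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$significant <- !is.na(p_used) & p_used < alpha_level
  res
}

#' @export
print.sfa_ranking <- function(x, ...) {
  cat(sprintf("<sfa_ranking> %s ~ morphometry in %s (mean of %s)\n",
              attr(x, "test"), attr(x, "cohort"),
              paste(attr(x, "ensembles_used"), collapse = ", ")))
  NextMethod()
}

#' @describeIn rank_features Ranking entries as a plain tibble.
#' @param x,... Method arguments.
#' @method tidy sfa_ranking
#' @export
tidy.sfa_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}
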