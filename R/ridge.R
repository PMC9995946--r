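# Cohort-specific ridge regressions from morphometry to test scores: the
# "SFA stamp" of a diagnostic group.

#' Fit a cohort-specific structure-function association model
#'
#' Ridge regression of one cognitive test score on the morphometric features
#' of one cohort: coefficients minimise \eqn{\|y - Xw - b\|^2 + \alpha
#' \|w\|^2} with the intercept unpenalised and features z-scored on the
#' training data.  The default penalty is \eqn{\alpha = 0.5}.  Solved by
#' least squares on the \eqn{\sqrt{\alpha}}-augmented design (QR), so the
#' fit is deterministic.
#'
#' @param data Subject-level tibble (see [generate_cohorts()] or
#'   [load_subject_table()]).
#' @param cohort `"CN"`, `"MCI"` or `"Dementia"`; only this cohort's rows
#'   with a non-missing score enter the fit.
#' @param test One of `test_scales()$name`.
#' @param feature_set `"VBM"`, `"SBM"` or `"VBM+SBM"`.
#' @param alpha Ridge penalty, must be positive.
#' @return An object of class `sfa_model` with named `coefficients` (on the
#'   standardized scale), `intercept`, the per-feature standardisation, and
#'   fit metadata.  Features with zero training variance are dropped with a
#'   warning.
#' @seealso [predict_score()], [evaluate_model_cv()], [build_model_bank()]
#' @export
fit_sfa_model <- function(data, cohort, test, feature_set = "VBM",
                          alpha = 0.5) {
  assert_cohort(cohort)
  assert_test(test)
  feature_set <- match.arg(feature_set, c("VBM", "SBM", "VBM+SBM"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a positive number", call. = FALSE)
  }
  feats <- feature_columns(data, feature_set)
  if (length(feats) == 0) {
    stop("no `", feature_set, "` feature columns in `data`", call. = FALSE)
  }
  d <- data[data$cohort == cohort & !is.na(data[[test]]), , drop = FALSE]
  d <- d[complete.cases(d[, feats]), , drop = FALSE]
  if (nrow(d) < 2) {
    stop("need at least 2 usable ", cohort, " records with a ", test,
         " score to fit", call. = FALSE)
  }
  X <- as.matrix(d[, feats])
  y <- d[[test]]

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  dead <- !is.finite(scl) | scl <= 0
  if (any(dead)) {
    warning("dropping zero-variance feature(s): ",
            paste(feats[dead], collapse = ", "), call. = FALSE)
    X <- X[, !dead, drop = FALSE]
    feats <- feats[!dead]
    ctr <- ctr[!dead]
    scl <- scl[!dead]
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)
  p <- ncol(Xs)
  aug <- rbind(Xs, sqrt(alpha) * diag(p))
  w <- qr.solve(aug, c(yc, rep(0, p)))

  structure(list(
    cohort = cohort, test = test, feature_set = feature_set, alpha = alpha,
    coefficients = setNames(as.numeric(w), feats),
    intercept = mean(y),
    center = setNames(as.numeric(ctr), feats),
    scale = setNames(as.numeric(scl), feats),
    n = nrow(d),
    subjects = unique(as.character(d$subject_id))
  ), class = "sfa_model")
}

#' Predict a test score from morphometric features
#'
#' Returns `intercept + coefficients %*% standardized(features)`.
#' Predictions are deliberately *not* clipped to the scale bounds: the raw
#' residual geometry is what the best-fit classifier compares across cohort
#' models.
#'
#' @param model An `sfa_model`.
#' @param newdata A tibble (or named list coercible to one) containing every
#'   feature column the model uses.
#' @return Numeric vector of predicted scores.
#' @export
predict_score <- function(model, newdata) {
  stopifnot(inherits(model, "sfa_model"))
  newdata <- tibble::as_tibble(newdata)
  feats <- names(model$coefficients)
  missing <- setdiff(feats, names(newdata))
  if (length(missing) > 0) {
    stop("missing feature(s) required for prediction: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  X <- as.matrix(newdata[, feats, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.numeric(model$intercept + Xs %*% model$coefficients)
}

#' @export
predict.sfa_model <- function(object, newdata, ...) {
  predict_score(object, newdata)
}

#' @export
print.sfa_model <- function(x, ...) {
  cat(sprintf("<sfa_model> %s ~ %s morphometry in %s (alpha = %g, n = %d, %d features)\n",
              x$test, x$feature_set, x$cohort, x$alpha, x$n,
              length(x$coefficients)))
  invisible(x)
}

#' @describeIn fit_sfa_model Coefficients as a tibble (`term`, `estimate`;
#'   standardized scale, intercept included).
#' @param x,... Method arguments.
#' @method tidy sfa_model
#' @export
tidy.sfa_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @describeIn fit_sfa_model One-row fit summary.
#' @method glance sfa_model
#' @export
glance.sfa_model <- function(x, ...) {
  tibble::tibble(cohort = x$cohort, test = x$test,
                 feature_set = x$feature_set, alpha = x$alpha,
                 n = x$n, n_features = length(x$coefficients))
}
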