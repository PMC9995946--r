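# Best-fitting-SFA-pattern screening: a subject is assigned to the cohort
# whose regression predicts their actual scores with the smallest absolute
# residual, per test, and the per-test votes are fused by majority.

#' Build a bank of cohort-specific SFA models
#'
#' Fits one ridge model per (cohort, test) on the training data and stores
#' the per-test empirical score ranges (for residual normalisation) and the
#' training subject ids (for leakage checks).
#'
#' @inheritParams fit_sfa_model
#' @param train Training dataset.
#' @param tests Ordered character vector of tests used for voting.  The
#'   default `c("MMSE", "ADAS13", "RAVLT_imm")` is the trio under which
#'   majority voting performs best; all five tests are supported.
#' @return An object of class `sfa_model_bank`.
#' @export
build_model_bank <- function(train, tests = c("MMSE", "ADAS13", "RAVLT_imm"),
                             feature_set = "VBM", alpha = 0.5) {
  tests <- vapply(tests, assert_test, character(1))
  models <- list()
  for (t in tests) {
    models[[t]] <- lapply(setNames(nm = cohort_levels()), function(g) {
      fit_sfa_model(train, g, t, feature_set, alpha)
    })
  }
  structure(list(
    models = models,
    tests = unname(tests),
    feature_set = feature_set,
    alpha = alpha,
    ranges = vapply(tests, function(t) empirical_range(train, t),
                    numeric(1)),
    train_subjects = unique(as.character(train$subject_id))
  ), class = "sfa_model_bank")
}

#' @export
print.sfa_model_bank <- function(x, ...) {
  cat(sprintf("<sfa_model_bank> %s models for %s (alpha = %g, %d training subjects)\n",
              x$feature_set, paste(x$tests, collapse = ", "), x$alpha,
              length(x$train_subjects)))
  invisible(x)
}

#' Per-cohort absolute residuals for one test
#'
#' For every record with an observed score, computes
#' \eqn{r_g = |\hat y_g - y|} under each cohort's model, plus the residual
#' normalised by the test's empirical range (so residuals are comparable
#' across tests during tie-breaking).  Records missing the score are
#' skipped — that test simply contributes no vote for them.
#'
#' @param bank An `sfa_model_bank`.
#' @param data Subject-level tibble.
#' @param test One of `bank$tests`.
#' @return A long tibble: `subject_id`, `test`, `model_cohort`, `residual`,
#'   `norm_residual`.
#' @export
residuals_for_test <- function(bank, data, test) {
  stopifnot(inherits(bank, "sfa_model_bank"))
  if (!test %in% bank$tests) {
    stop("`test` must be one of the bank's tests: ",
         paste(bank$tests, collapse = ", "), call. = FALSE)
  }
  d <- data[!is.na(data[[test]]), , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble::tibble(subject_id = character(), test = character(),
                          model_cohort = character(), residual = numeric(),
                          norm_residual = numeric()))
  }
  purrr::map(cohort_levels(), function(g) {
    pred <- predict_score(bank$models[[test]][[g]], d)
    tibble::tibble(subject_id = as.character(d$subject_id), test = test,
                   model_cohort = g,
                   residual = abs(pred - d[[test]]),
                   norm_residual = abs(pred - d[[test]]) / bank$ranges[[test]])
  }) |>
    dplyr::bind_rows()
}

#' Vote for the cohort whose model fits best
#'
#' The minimal absolute residual identifies the cohort.  Exact ties are
#' broken toward the less severe label (CN over MCI over Dementia) and
#' flagged.
#'
#' @param residuals Named numeric vector of per-cohort residuals
#'   (`CN`, `MCI`, `Dementia`); non-finite entries are treated as skipped
#'   models.
#' @param tol Absolute tolerance within which residuals count as tied.
#' @return A list with `vote` (cohort label) and `tie_broken` (logical).
#' @export
vote_for_test <- function(residuals, tol = 1e-9) {
  r <- residuals[cohort_levels()]
  finite <- is.finite(r)
  if (!any(finite)) {
    stop("no finite residual to vote on", call. = FALSE)
  }
  m <- min(r[finite])
  tied <- finite & (r - m <= tol)
  list(vote = cohort_levels()[which(tied)[1]],
       tie_broken = sum(tied) > 1L)
}

# internal: fuse per-test votes into a final label
# votes: character vector of cohort labels; win_norm: the winning vote's
# normalised residual per test
fuse_votes <- function(votes, win_norm) {
  tab <- table(factor(votes, levels = cohort_levels()))
  leaders <- names(tab)[tab == max(tab)]
  if (length(leaders) == 1L) {
    return(list(label = leaders, tie_broken = FALSE))
  }
  in_play <- votes %in% leaders
  best <- votes[in_play][which.min(win_norm[in_play])]
  list(label = best, tie_broken = TRUE)
}

#' Classify subjects by their best-fitting SFA pattern
#'
#' Computes per-test cohort votes ([vote_for_test()]) for every record and
#' fuses them by majority voting.  Vote ties among leading labels are broken
#' by the smallest range-normalised residual among the tied winning votes;
#' the tie-break is recorded.
#'
#' @inheritParams residuals_for_test
#' @param tests Tests to vote with (default: the bank's test list).
#' @return A tibble with one row per usable record: `subject_id`, the true
#'   `cohort` when present in `data`, one `vote_<test>` column per test
#'   (`NA` where the score was missing), `final_label`, and `tie_broken`.
#'   Records with no usable test are dropped with a warning.
#' @export
classify_subjects <- function(bank, data, tests = NULL) {
  stopifnot(inherits(bank, "sfa_model_bank"))
  tests <- tests %||% bank$tests
  bad <- setdiff(tests, bank$tests)
  if (length(bad) > 0) {
    stop("bank has no models for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  ids <- as.character(data$subject_id)
  votes <- matrix(NA_character_, n, length(tests),
                  dimnames = list(NULL, tests))
  win_norm <- matrix(NA_real_, n, length(tests), dimnames = list(NULL, tests))
  any_tie <- rep(FALSE, n)
  for (t in tests) {
    usable <- which(!is.na(data[[t]]))
    if (length(usable) == 0) next
    d <- data[usable, , drop = FALSE]
    res <- vapply(cohort_levels(), function(g) {
      abs(predict_score(bank$models[[t]][[g]], d) - d[[t]])
    }, numeric(length(usable)))
    res <- matrix(res, ncol = 3, dimnames = list(NULL, cohort_levels()))
    mins <- apply(res, 1, min)
    tied <- (res - mins) <= 1e-9
    pick <- apply(tied, 1, function(z) which(z)[1])  # severity preference
    votes[usable, t] <- cohort_levels()[pick]
    win_norm[usable, t] <- mins / bank$ranges[[t]]
    any_tie[usable] <- any_tie[usable] | rowSums(tied) > 1
  }
  usable_rows <- rowSums(!is.na(votes)) > 0
  if (!all(usable_rows)) {
    warning(sum(!usable_rows), " record(s) had no usable test and were ",
            "dropped", call. = FALSE)
  }
  out <- tibble::tibble(subject_id = ids[usable_rows])
  if ("cohort" %in% names(data)) {
    out$cohort <- factor(as.character(data$cohort)[usable_rows],
                         levels = cohort_levels())
  }
  fused <- purrr::map(which(usable_rows), function(i) {
    ok <- !is.na(votes[i, ])
    fuse_votes(votes[i, ok], win_norm[i, ok])
  })
  for (t in tests) {
    out[[paste0("vote_", t)]] <- votes[usable_rows, t]
  }
  out$final_label <- factor(purrr::map_chr(fused, "label"),
                            levels = cohort_levels())
  out$tie_broken <- purrr::map_lgl(fused, "tie_broken") |
    any_tie[usable_rows]
  out
}

#' Confusion matrix and per-class true-positive rates
#'
#' @param true,assigned Vectors of cohort labels.
#' @return An object of class `sfa_confusion`: 3x3 `counts`
#'   (true x assigned) and `tpr` (percent, per true class).
#' @export
confusion_matrix <- function(true, assigned) {
  true <- factor(as.character(true), levels = cohort_levels())
  assigned <- factor(as.character(assigned), levels = cohort_levels())
  counts <- table(true = true, assigned = assigned)
  tpr <- 100 * diag(counts) / pmax(rowSums(counts), 1)
  structure(list(counts = unclass(counts), tpr = tpr,
                 n = sum(counts)), class = "sfa_confusion")
}

#' Evaluate the screening classifier on held-out subjects
#'
#' Classifies every usable record of `eval_data` and tabulates the 3x3
#' confusion matrix with per-class true-positive rates.  Evaluation subjects
#' must be disjoint from the bank's training subjects; overlap raises an
#' error unless explicitly overridden.
#'
#' @inheritParams classify_subjects
#' @param eval_data Held-out dataset with true `cohort` labels.
#' @param allow_overlap Set `TRUE` to evaluate despite train/eval subject
#'   overlap (a loud warning is kept).
#' @return An `sfa_confusion`.
#' @export
evaluate_classifier <- function(bank, eval_data, tests = NULL,
                                allow_overlap = FALSE) {
  overlap <- intersect(unique(as.character(eval_data$subject_id)),
                       bank$train_subjects)
  if (length(overlap) > 0) {
    if (!allow_overlap) {
      stop(length(overlap), " evaluation subject(s) were used to train the ",
           "bank; refusing to evaluate (set `allow_overlap = TRUE` to ",
           "override)", call. = FALSE)
    }
    warning("evaluating with ", length(overlap), " subject(s) that appear ",
            "in the training data: TPRs will be optimistic", call. = FALSE)
  }
  if (!"cohort" %in% names(eval_data)) {
    stop("`eval_data` must carry true `cohort` labels", call. = FALSE)
  }
  vr <- classify_subjects(bank, eval_data, tests)
  confusion_matrix(vr$cohort, vr$final_label)
}

#' @export
print.sfa_confusion <- function(x, ...) {
  cat("<sfa_confusion> n =", x$n, "\n")
  print(x$counts)
  cat("TPR (%):", paste(sprintf("%s %.2f", names(x$tpr), x$tpr),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn confusion_matrix Counts in long form.
#' @param x,... Method arguments.
#' @method tidy sfa_confusion
#' @export
tidy.sfa_confusion <- function(x, ...) {
  as.data.frame(as.table(x$counts), responseName = "n") |>
    tibble::as_tibble()
}

#' @describeIn confusion_matrix One-row summary with per-class TPR (%) and
#'   overall accuracy (%).
#' @method glance sfa_confusion
#' @export
glance.sfa_confusion <- function(x, ...) {
  tibble::tibble(
    tpr_cn = x$tpr[["CN"]], tpr_mci = x$tpr[["MCI"]],
    tpr_dementia = x$tpr[["Dementia"]],
    accuracy = 100 * sum(diag(x$counts)) / x$n,
    n = x$n
  )
}
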