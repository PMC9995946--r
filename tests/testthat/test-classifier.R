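# a bank of intercept-only models with fixed predictions per cohort
constant_bank <- function(preds = list(MMSE = c(CN = 28, MCI = 25, Dementia = 21)),
                          ranges = c(MMSE = 18)) {
  tests <- names(preds)
  models <- lapply(preds, function(p) {
    lapply(setNames(nm = cohort_levels()), function(g) {
      structure(list(cohort = g, test = "x", feature_set = "VBM",
                     alpha = 0.5,
                     coefficients = setNames(0, "vbm_f1"),
                     intercept = p[[g]],
                     center = setNames(0, "vbm_f1"),
                     scale = setNames(1, "vbm_f1"),
                     n = 2, subjects = character(0)),
                class = "sfa_model")
    })
  })
  structure(list(models = models, tests = tests, feature_set = "VBM",
                 alpha = 0.5, ranges = ranges[tests],
                 train_subjects = character(0)),
            class = "sfa_model_bank")
}

test_that("per-cohort residuals are plain absolute differences", {
  bank <- constant_bank()
  subject <- tibble::tibble(subject_id = "p1", MMSE = 24, vbm_f1 = 0)
  res <- residuals_for_test(bank, subject, "MMSE")
  expect_equal(setNames(res$residual, res$model_cohort),
               c(CN = 4, MCI = 1, Dementia = 3))
  expect_equal(res$norm_residual, res$residual / 18)
})

test_that("the minimal residual identifies the cohort, ties break mild-first", {
  expect_equal(vote_for_test(c(CN = 4, MCI = 1, Dementia = 3)),
               list(vote = "MCI", tie_broken = FALSE))
  expect_equal(vote_for_test(c(CN = 2, MCI = 2, Dementia = 5)),
               list(vote = "CN", tie_broken = TRUE))
  expect_equal(vote_for_test(c(CN = NA, MCI = Inf, Dementia = 0.7))$vote,
               "Dementia")
  expect_error(vote_for_test(c(CN = NA, MCI = NA, Dementia = NA)),
               "no finite residual")
})

test_that("majority voting fuses per-test votes with documented tie-breaks", {
  f <- sfascreen:::fuse_votes
  expect_equal(f(c("CN", "CN", "MCI"), c(0.2, 0.1, 0.05)),
               list(label = "CN", tie_broken = FALSE))
  # three-way tie: smallest normalised winning residual decides
  expect_equal(f(c("CN", "MCI", "Dementia"), c(0.10, 0.03, 0.20)),
               list(label = "MCI", tie_broken = TRUE))
  # two-way tie among leaders
  expect_equal(f(c("CN", "CN", "MCI", "MCI", "Dementia"),
                 c(0.2, 0.3, 0.01, 0.5, 0.001)),
               list(label = "MCI", tie_broken = TRUE))
})

test_that("missing scores skip the test and fully unusable records warn", {
  bank <- constant_bank(preds = list(
    MMSE = c(CN = 28, MCI = 25, Dementia = 21),
    ADAS13 = c(CN = 10, MCI = 18, Dementia = 30)),
    ranges = c(MMSE = 18, ADAS13 = 64))
  d <- tibble::tibble(subject_id = c("a", "b"),
                      cohort = factor(c("CN", "MCI"),
                                      levels = cohort_levels()),
                      MMSE = c(NA, 26), ADAS13 = c(11, NA), vbm_f1 = 0)
  out <- classify_subjects(bank, d)
  expect_equal(out$vote_MMSE, c(NA, "MCI"))
  expect_equal(out$vote_ADAS13, c("CN", NA))
  expect_equal(as.character(out$final_label), c("CN", "MCI"))
  d$ADAS13[1] <- NA
  d$MMSE[1] <- NA
  expect_warning(out2 <- classify_subjects(bank, d), "no usable test")
  expect_equal(out2$subject_id, "b")
})

test_that("confusion counts and TPRs follow the definition", {
  true <- c(rep("CN", 88), rep("MCI", 10), rep("Dementia", 10))
  assigned <- c(rep("CN", 74), rep("MCI", 13), rep("Dementia", 1),
                rep("MCI", 10), rep("Dementia", 10))
  cm <- confusion_matrix(true, assigned)
  expect_equal(cm$counts["CN", ], c(CN = 74, MCI = 13, Dementia = 1))
  expect_equal(cm$tpr[["CN"]], 100 * 74 / 88, tolerance = 1e-12)
  expect_equal(unname(rowSums(cm$counts)), c(88, 10, 10))
  expect_equal(glance(cm)$accuracy, 100 * 94 / 108, tolerance = 1e-12)
})

test_that("noise-free generation is recovered perfectly end to end", {
  train <- sim_data(n = 80, seed = 50, noise = 0)
  held <- sim_data(n = 80, seed = 51, noise = 0)
  bank <- build_model_bank(train, feature_set = "VBM")
  cm <- evaluate_classifier(bank, held)
  expect_equal(unname(cm$tpr), c(100, 100, 100))
})

test_that("train/evaluation subject overlap is refused unless overridden", {
  d <- sim_data(n = 40, seed = 52)
  bank <- build_model_bank(d, feature_set = "VBM")
  expect_error(evaluate_classifier(bank, d), "refusing")
  expect_warning(cm <- evaluate_classifier(bank, d, allow_overlap = TRUE),
                 "optimistic")
  expect_equal(cm$n, nrow(d))
})

test_that("classification is deterministic and row counts are conserved", {
  train <- sim_data(n = 60, seed = 53)
  held <- sim_data(n = 60, seed = 54)
  bank <- build_model_bank(train, feature_set = "VBM")
  v1 <- classify_subjects(bank, held)
  v2 <- classify_subjects(bank, held)
  expect_identical(v1, v2)
  cm <- evaluate_classifier(bank, held)
  expect_equal(unname(rowSums(cm$counts)), rep(60, 3))
  expect_true(all(as.character(v1$final_label) %in% cohort_levels()))
})

test_that("majority voting beats the worst single test on average", {
  per_seed <- sapply(1:20, function(s) {
    train <- sim_data(n = 150, seed = 900 + 2 * s)
    held <- sim_data(n = 150, seed = 901 + 2 * s)
    bank <- build_model_bank(train, feature_set = "VBM")
    maj <- evaluate_classifier(bank, held)$tpr
    singles <- sapply(bank$tests, function(t) {
      evaluate_classifier(bank, held, tests = t)$tpr
    })
    maj - apply(singles, 1, min)
  })
  expect_true(all(rowMeans(per_seed) >= 0))
})

test_that("accuracy degrades monotonically with increasing noise", {
  acc <- sapply(c(0, 0.5, 1, 2), function(f) {
    mean(sapply(1:8, function(s) {
      train <- sim_data(n = 100, seed = 700 + 2 * s, noise = f)
      held <- sim_data(n = 100, seed = 701 + 2 * s, noise = f)
      bank <- build_model_bank(train, feature_set = "VBM")
      glance(evaluate_classifier(bank, held))$accuracy
    }))
  })
  expect_true(all(diff(acc) <= 0))
})
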