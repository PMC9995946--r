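test_that("a single planted signal dominates the aggregated ranking", {
  d <- manual_cohort_data(n = 150, p = 8, seed = 30)
  d$MMSE <- d$vbm_f3
  rk <- rank_features(d, "CN", "MMSE", "VBM", seed = 1, num_trees = 200,
                      xgb_rounds = 100, adaboost_rounds = 25)
  expect_equal(rk$feature[1], "vbm_f3")
  expect_gt(rk$importance[1], 0.9)
})

test_that("per-ensemble and aggregated importances are normalised and sorted", {
  d <- manual_cohort_data(n = 120, p = 6, seed = 31)
  set.seed(310)
  d$DSST <- 40 + 2 * d$vbm_f1 + d$vbm_f2 + rnorm(120, 0, 1)
  rk <- rank_features(d, "CN", "DSST", "VBM", seed = 2, num_trees = 200,
                      xgb_rounds = 100, adaboost_rounds = 25)
  for (col in c("importance", "random_forest", "extra_trees",
                "gradient_boosting", "adaboost")) {
    expect_equal(sum(rk[[col]]), 1, tolerance = 1e-6)
    expect_true(all(rk[[col]] >= 0))
  }
  expect_true(all(diff(rk$importance) <= 1e-12))
  expect_equal(attr(rk, "ensembles_used"),
               c("random_forest", "extra_trees", "gradient_boosting",
                 "adaboost"))
})

test_that("two planted signals with 3:1 weights surface in the top three", {
  hits <- sapply(1:10, function(s) {
    d <- manual_cohort_data(n = 150, p = 8, seed = 500 + s)
    set.seed(600 + s)
    d$RAVLT_imm <- 3 * d$vbm_f1 + d$vbm_f2 + rnorm(150, 0, 0.3)
    rk <- rank_features(d, "CN", "RAVLT_imm", "VBM", seed = s,
                        num_trees = 200, xgb_rounds = 100,
                        adaboost_rounds = 25)
    all(c("vbm_f1", "vbm_f2") %in% rk$feature[1:3])
  })
  expect_true(all(hits))
})

test_that("a pure-noise outcome stays close to uniform importance", {
  flat <- sapply(1:10, function(s) {
    d <- manual_cohort_data(n = 150, p = 20, seed = 700 + s)
    set.seed(800 + s)
    d$TMT_B <- rnorm(150, 120, 20)
    rk <- rank_features(d, "CN", "TMT_B", "VBM", seed = s, num_trees = 200,
                        xgb_rounds = 100, adaboost_rounds = 25)
    max(rk$importance) <= 3 / 20
  })
  expect_gte(sum(flat), 8)
})

test_that("the ranking is invariant to feature column order", {
  d <- manual_cohort_data(n = 100, p = 6, seed = 32)
  set.seed(320)
  d$MMSE <- 27 + d$vbm_f5 + rnorm(100, 0, 0.5)
  shuffled <- d[, c("subject_id", "cohort",
                    sample(paste0("vbm_f", 1:6)), "MMSE")]
  rk1 <- rank_features(d, "CN", "MMSE", "VBM", seed = 3, num_trees = 100,
                       xgb_rounds = 50, adaboost_rounds = 10)
  rk2 <- rank_features(shuffled, "CN", "MMSE", "VBM", seed = 3,
                       num_trees = 100, xgb_rounds = 50,
                       adaboost_rounds = 10)
  expect_equal(rk1$feature, rk2$feature)
  expect_equal(rk1$importance, rk2$importance)
})

test_that("a constant outcome cannot be ranked", {
  d <- manual_cohort_data(n = 40, p = 4)
  d$MMSE <- 27
  expect_error(rank_features(d, "CN", "MMSE", "VBM"), "constant")
})

test_that("regional correlations reproduce hand-computed Pearson values", {
  d <- manual_cohort_data(n = 5, p = 2, seed = 33)
  d$vbm_ctx_test <- 1:5
  d$MMSE <- c(2, 1, 4, 3, 5)
  res <- correlate_regions(d, "CN", "MMSE")
  expect_equal(res$r[res$region == "vbm_ctx_test"], 0.8, tolerance = 1e-12)
})

test_that("affine relations give perfect correlations with matching sign", {
  d <- manual_cohort_data(n = 20, p = 2, seed = 34)
  set.seed(340)
  d$MMSE <- rnorm(20, 27, 1.5)
  d$vbm_ctx_pos <- 2 * d$MMSE + 1
  d$vbm_ctx_neg <- -d$MMSE
  res <- correlate_regions(d, "CN", "MMSE")
  expect_equal(res$r[res$region == "vbm_ctx_pos"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$region == "vbm_ctx_neg"], -1, tolerance = 1e-12)
  expect_true(all(res$significant[res$region %in%
                                    c("vbm_ctx_pos", "vbm_ctx_neg")]))
})

test_that("opposite scoring directions flip the sign of a planted signal", {
  d <- manual_cohort_data(n = 100, p = 2, seed = 35)
  set.seed(350)
  atrophy <- rnorm(100)
  d$vbm_ctx_region <- 3 + atrophy
  d$MMSE <- 27 + 2 * atrophy + rnorm(100, 0, 0.5)       # higher is better
  d$ADAS13 <- 15 - 3 * atrophy + rnorm(100, 0, 0.5)     # lower is better
  r_hi <- correlate_regions(d, "CN", "MMSE")
  r_lo <- correlate_regions(d, "CN", "ADAS13")
  expect_gt(r_hi$r[r_hi$region == "vbm_ctx_region"], 0)
  expect_lt(r_lo$r[r_lo$region == "vbm_ctx_region"], 0)
})

test_that("zero-variance regions are flagged missing, never significant", {
  d <- manual_cohort_data(n = 30, p = 2, seed = 36)
  set.seed(360)
  d$MMSE <- rnorm(30, 27, 1)
  d$vbm_ctx_flat <- 5
  res <- correlate_regions(d, "CN", "MMSE")
  expect_true(is.na(res$r[res$region == "vbm_ctx_flat"]))
  expect_false(res$significant[res$region == "vbm_ctx_flat"])
})
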