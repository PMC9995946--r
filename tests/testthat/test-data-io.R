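write_mini_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

mini_schema <- function() {
  list(subject_id = "id", age = "age", cohort = "dx",
       scores = c(MMSE = "mmse"),
       features = c(vbm_hippocampus = "hippo"))
}

test_that("a written dataset round-trips through load_subject_table", {
  d <- sim_data(n = 8, seed = 5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_subject_table(d, path)
  back <- load_subject_table(path, identity_schema(d))
  expect_equal(back$subject_id, d$subject_id)
  expect_equal(as.character(back$cohort), as.character(d$cohort))
  expect_equal(back$age, d$age)
  for (col in c("MMSE", "DSST", "vbm_hippocampus", "sbm_thick_entorhinal")) {
    expect_equal(back[[col]], d[[col]], tolerance = 1e-12)
  }
})

test_that("cohort aliases map clinical labels onto the three-class set", {
  path <- write_mini_csv(c("id,age,dx,mmse,hippo",
                           "s1,72,AD,22,0.25",
                           "s2,70,LMCI,27,0.28",
                           "s3,68,CN,29,0.30"))
  d <- load_subject_table(path, mini_schema())
  expect_equal(as.character(d$cohort), c("Dementia", "MCI", "CN"))
})

test_that("scores beyond the scale ceiling are rejected with the bound named", {
  path <- write_mini_csv(c("id,age,dx,mmse,hippo", "s1,72,CN,35,0.25"))
  expect_error(load_subject_table(path, mini_schema()), "30")
  expect_error(load_subject_table(path, mini_schema()), "MMSE")
})

test_that("schema and input errors are specific", {
  path <- write_mini_csv(c("id,age,dx,mmse,hippo", "s1,72,CN,29,0.25"))
  bad <- mini_schema()
  bad$age <- "not_there"
  expect_error(load_subject_table(path, bad), "schema error")
  expect_error(load_subject_table(path, list(subject_id = "id")),
               "schema error")
  empty <- write_mini_csv("id,age,dx,mmse,hippo")
  expect_error(load_subject_table(empty, mini_schema()), "no data rows")
  unk <- write_mini_csv(c("id,age,dx,mmse,hippo", "s1,72,HD,29,0.25"))
  expect_error(load_subject_table(unk, mini_schema()), "row 1")
  old <- write_mini_csv(c("id,age,dx,mmse,hippo", "s1,130,CN,29,0.25"))
  expect_error(load_subject_table(old, mini_schema()), "age")
})

test_that("cells failing numeric coercion are reported, not dropped", {
  path <- write_mini_csv(c("id,age,dx,mmse,hippo",
                           "s1,72,CN,oops,0.25",
                           "s2,75,MCI,26,0.27"))
  expect_warning(d <- load_subject_table(path, mini_schema()),
                 "non-numeric MMSE")
  expect_equal(nrow(d), 2L)
  expect_true(is.na(d$MMSE[1]))
  expect_equal(d$MMSE[2], 26)
})

converter_data <- function() {
  d <- manual_cohort_data(n = 10, p = 2, seed = 7)
  # one subject observed as CN then MCI (a diagnostic converter)
  d$subject_id[2] <- d$subject_id[1]
  d$cohort <- factor(c("CN", "MCI", rep("CN", 8)), levels = cohort_levels())
  # two segmentation failures: all features missing
  d[9:10, c("vbm_f1", "vbm_f2")] <- NA_real_
  d
}

test_that("converters are removed entirely and failures counted", {
  d <- converter_data()
  out <- apply_cohort_filters(d, converter_policy = "drop")
  expect_equal(nrow(out), 6L)
  expect_false(d$subject_id[1] %in% out$subject_id)
  expect_equal(filter_report(out),
               c(segmentation_failure = 2L, converter = 2L))
  # conservation: input rows = output rows + removals
  expect_equal(nrow(d), nrow(out) + sum(filter_report(out)))
})

test_that("keeping converters only drops segmentation failures", {
  out <- apply_cohort_filters(converter_data(), converter_policy = "keep")
  expect_equal(nrow(out), 8L)
  expect_equal(filter_report(out)[["converter"]], 0L)
})

test_that("filtering is idempotent and a no-op on clean data", {
  clean <- manual_cohort_data(n = 6, p = 2, seed = 8)
  once <- apply_cohort_filters(clean)
  expect_equal(as.data.frame(once), as.data.frame(clean),
               ignore_attr = TRUE)
  expect_equal(sum(filter_report(once)), 0L)
  d <- converter_data()
  once <- apply_cohort_filters(d)
  twice <- apply_cohort_filters(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
})
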