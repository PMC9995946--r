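# Reading, validating and filtering subject-level tables.

default_cohort_aliases <- function() {
  c(CN = "CN", NL = "CN", MCI = "MCI", LMCI = "MCI", EMCI = "MCI",
    AD = "Dementia", Dementia = "Dementia")
}

#' Load and validate a delimited subject table
#'
#' Reads a CSV/TSV with one row per visit and maps its columns onto the
#' package's canonical layout via a `schema` list.  Scores are validated
#' against the nominal scale bounds ([test_scales()]), ages against
#' plausibility bounds (40-110 years), features against non-negativity, and
#' cohort labels against the three-class set after alias mapping.  Cells
#' that fail numeric coercion are set to `NA` and reported with a warning —
#' rows are never silently dropped.
#'
#' @param path Path to a delimited text file (`.csv` or `.tsv`).
#' @param schema A list with entries:
#'   * `subject_id`, `age`, `cohort` — required source column names;
#'   * `scores` — named character vector mapping test names
#'     (e.g. `MMSE`) to source columns (at least one);
#'   * `features` — named character vector mapping canonical feature names
#'     (e.g. `vbm_hippocampus`) to source columns (at least one);
#'   * optional `visit_index`, `sex`, `education`;
#'   * optional `cohort_aliases`, a named vector mapping source labels to
#'     `CN`/`MCI`/`Dementia` (defaults cover common ADNI spellings such as
#'     `AD` and `LMCI`).
#' @return A validated tibble with columns `subject_id`, `visit_index`,
#'   `age`, `sex`, `education`, `cohort`, the mapped scores and features.
#' @seealso [write_subject_table()], [identity_schema()],
#'   [apply_cohort_filters()]
#' @export
load_subject_table <- function(path, schema) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  for (req in c("subject_id", "age", "cohort")) {
    if (is.null(schema[[req]])) {
      stop("schema error: missing mapping for `", req, "`", call. = FALSE)
    }
  }
  if (length(schema$scores %||% character()) == 0 ||
      length(schema$features %||% character()) == 0) {
    stop("schema error: need at least one score and one feature mapping",
         call. = FALSE)
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  raw <- suppressWarnings(
    reader(path, col_types = readr::cols(.default = readr::col_character()),
           progress = FALSE, show_col_types = FALSE))
  if (nrow(raw) == 0) {
    stop("input error: `", path, "` contains no data rows", call. = FALSE)
  }
  wanted <- c(schema$subject_id, schema$age, schema$cohort,
              unname(schema$scores), unname(schema$features),
              schema$visit_index, schema$sex, schema$education)
  absent <- setdiff(wanted, names(raw))
  if (length(absent) > 0) {
    stop("schema error: column(s) not in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  coerce_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      warning("non-numeric ", what, " in row(s) ",
              paste(head(bad, 10), collapse = ", "),
              " set to NA", call. = FALSE)
    }
    out
  }

  out <- tibble::tibble(
    subject_id = as.character(raw[[schema$subject_id]]),
    visit_index = if (!is.null(schema$visit_index)) {
      as.integer(factor(raw[[schema$visit_index]],
                        levels = unique(raw[[schema$visit_index]])))
    } else {
      1L
    },
    age = coerce_num(raw[[schema$age]], "age"),
    sex = if (!is.null(schema$sex)) {
      factor(substr(toupper(as.character(raw[[schema$sex]])), 1, 1),
             levels = c("F", "M"))
    } else {
      factor(NA_character_, levels = c("F", "M"))
    },
    education = if (!is.null(schema$education)) {
      coerce_num(raw[[schema$education]], "education")
    } else {
      NA_real_
    }
  )

  aliases <- c(schema$cohort_aliases, default_cohort_aliases())
  lab <- as.character(raw[[schema$cohort]])
  mapped <- unname(aliases[lab])
  unknown <- which(is.na(mapped) | !mapped %in% cohort_levels())
  if (length(unknown) > 0) {
    stop("validation error: unknown cohort label `", lab[unknown[1]],
         "` in row ", unknown[1], call. = FALSE)
  }
  out$cohort <- factor(mapped, levels = cohort_levels())

  sc <- test_scales()
  for (t in names(schema$scores)) {
    assert_test(t)
    v <- coerce_num(raw[[schema$scores[[t]]]], t)
    i <- match(t, sc$name)
    bad <- which(!is.na(v) & (v < sc$min_score[i] | v > sc$max_score[i]))
    if (length(bad) > 0) {
      stop("validation error: ", t, " value ", v[bad[1]], " in row ",
           bad[1], " is outside the scale bounds [", sc$min_score[i], ", ",
           sc$max_score[i], "]", call. = FALSE)
    }
    out[[t]] <- v
  }

  for (f in names(schema$features)) {
    v <- coerce_num(raw[[schema$features[[f]]]], f)
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      stop("validation error: negative feature value for ", f, " in row ",
           bad[1], call. = FALSE)
    }
    out[[f]] <- v
  }

  bad_age <- which(!is.na(out$age) & (out$age < 40 | out$age > 110))
  if (length(bad_age) > 0) {
    stop("validation error: implausible age ", out$age[bad_age[1]],
         " in row ", bad_age[1], " (expected 40-110)", call. = FALSE)
  }
  attr(out, "sfa_provenance") <- "real"
  out
}

#' Write a subject table to delimited text
#'
#' Inverse of [load_subject_table()]: together with [identity_schema()] the
#' pair round-trips a dataset through disk.
#'
#' @param data Subject-level tibble.
#' @param path Output path (`.csv` or `.tsv` by extension).
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(data, path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path, progress = FALSE)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Identity schema for a canonical dataset
#'
#' Builds the [load_subject_table()] schema that maps a written canonical
#' dataset back onto itself.
#'
#' @param data Subject-level tibble in canonical layout.
#' @return A schema list.
#' @export
identity_schema <- function(data) {
  scores <- intersect(test_scales()$name, names(data))
  feats <- feature_columns(data, "VBM+SBM")
  list(
    subject_id = "subject_id", visit_index = "visit_index", age = "age",
    sex = "sex", education = "education", cohort = "cohort",
    scores = setNames(scores, scores),
    features = setNames(feats, feats)
  )
}

#' Apply the cohort inclusion filters
#'
#' Drops records whose segmentation failed (all feature values missing) and,
#' under `converter_policy = "drop"`, removes *all* records of any subject
#' that appears under more than one cohort label — diagnostic converters
#' must not contribute to cohort-specific models.  The removal counts per
#' reason are attached as a filter report.
#'
#' @param data Subject-level tibble.
#' @param converter_policy `"drop"` (default) or `"keep"`.
#' @return The filtered tibble; retrieve the accounting with
#'   [filter_report()].  Filtering is idempotent and total:
#'   `nrow(input) == nrow(output) + sum(report)`.
#' @export
apply_cohort_filters <- function(data, converter_policy = c("drop", "keep")) {
  converter_policy <- match.arg(converter_policy)
  feats <- feature_columns(data, "VBM+SBM")
  seg_fail <- if (length(feats) > 0) {
    rowSums(!is.na(data[, feats, drop = FALSE])) == 0
  } else {
    rep(FALSE, nrow(data))
  }
  kept <- data[!seg_fail, , drop = FALSE]
  n_conv <- 0L
  if (converter_policy == "drop" && nrow(kept) > 0) {
    n_labels <- tapply(as.character(kept$cohort),
                       as.character(kept$subject_id),
                       function(x) length(unique(x)))
    converters <- names(n_labels)[n_labels > 1]
    is_conv <- as.character(kept$subject_id) %in% converters
    n_conv <- sum(is_conv)
    kept <- kept[!is_conv, , drop = FALSE]
  }
  attr(kept, "sfa_filter_report") <- c(segmentation_failure = sum(seg_fail),
                                       converter = n_conv)
  attr(kept, "sfa_provenance") <- attr(data, "sfa_provenance")
  kept
}

#' Retrieve the filter accounting of [apply_cohort_filters()]
#'
#' @param data A filtered dataset.
#' @return Named integer vector of removal counts per reason.
#' @export
filter_report <- function(data) {
  rep <- attr(data, "sfa_filter_report")
  if (is.null(rep)) {
    stop("`data` carries no filter report; run `apply_cohort_filters()` ",
         "first", call. = FALSE)
  }
  rep
}
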