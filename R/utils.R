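#' Diagnostic cohort labels
#'
#' @return `c("CN", "MCI", "Dementia")`, the three-class label set in
#'   increasing order of severity.
#' @export
cohort_levels <- function() c("CN", "MCI", "Dementia")

assert_cohort <- function(cohort) {
  if (!is.character(cohort) || length(cohort) != 1L ||
      !cohort %in% cohort_levels()) {
    stop("`cohort` must be one of ", paste(cohort_levels(), collapse = ", "),
         call. = FALSE)
  }
  cohort
}

assert_test <- function(test) {
  nm <- test_scales()$name
  if (!is.character(test) || length(test) != 1L || !test %in% nm) {
    stop("`test` must be one of ", paste(nm, collapse = ", "), call. = FALSE)
  }
  test
}

scale_bounds <- function(test) {
  sc <- test_scales()
  i <- match(test, sc$name)
  c(sc$min_score[i], sc$max_score[i])
}

scale_direction <- function(test) {
  sc <- test_scales()
  sc$direction[match(test, sc$name)]
}

clip_to <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# mean of a N(mu, sd) variable clipped to [lo, hi] (closed form)
clipped_normal_mean <- function(mu, sd, lo, hi) {
  if (sd <= 0) return(clip_to(mu, lo, hi))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) + sd * (dnorm(a) - dnorm(b))
}
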