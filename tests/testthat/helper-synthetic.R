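# shared fixtures, all built in code

# balanced synthetic cohorts; noise = 0 gives the deterministic limit
sim_data <- function(n = 100, seed = 1, noise = 1, null = FALSE, ...) {
  cfg <- if (null) {
    null_sim_config(n_per_cohort = c(CN = n, MCI = n, Dementia = n),
                    seed = seed)
  } else {
    sfa_sim_config(n_per_cohort = c(CN = n, MCI = n, Dementia = n),
                   seed = seed, ...)
  }
  if (noise != 1) cfg <- scale_noise(cfg, noise)
  generate_cohorts(cfg)
}

# minimal hand-built cohort table with iid standard-normal "vbm_f*" features
manual_cohort_data <- function(n = 30, p = 6, seed = 1, cohort = "CN") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("vbm_f", seq_len(p))))
  d <- tibble::as_tibble(X)
  d$subject_id <- sprintf("S-%s-%03d", cohort, seq_len(n))
  d$cohort <- factor(cohort, levels = cohort_levels())
  d[, c("subject_id", "cohort", colnames(X))]
}

# closed-form ridge oracle: solve the penalized normal equations directly
ridge_oracle <- function(X, y, alpha) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)
  drop(solve(crossprod(Xs) + alpha * diag(ncol(Xs)), crossprod(Xs, yc)))
}

fs_fixture <- function(name) {
  system.file("extdata", name, package = "sfascreen", mustWork = TRUE)
}
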