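# Three-cohort synthetic data generator with planted structure-function
# associations.  Cohort score distributions, age slopes and gray-matter
# atrophy trends are calibrated to published ADNI1 cohort summary statistics;
# DSST/TMT trendlines are constrained to intersect at a common convergence
# age, mirroring the converging neuropsychological decline observed across
# CN, MCI and dementia cohorts.

tests_in_order <- function() test_scales()$name

# Published cohort summaries used as calibration targets (rows CN/MCI/Dementia)
adni_score_means <- function() {
  m <- rbind(
    CN       = c(29.06,  8.73, 43.20,  85.03, 46.77),
    MCI      = c(26.91, 18.82, 29.79, 128.48, 37.37),
    Dementia = c(22.66, 30.37, 21.67, 200.96, 26.05)
  )
  colnames(m) <- tests_in_order()
  m
}

adni_score_sds <- function() {
  m <- rbind(
    CN       = c(1.09, 4.14, 9.76, 43.18, 11.06),
    MCI      = c(2.20, 6.60, 8.86, 72.56, 11.10),
    Dementia = c(3.03, 8.97, 7.77, 88.57, 12.41)
  )
  colnames(m) <- tests_in_order()
  m
}

# Within-CN age slopes (points/year) and CN-vs-group interaction estimates
adni_cn_slopes <- function() {
  c(MMSE = -0.005, ADAS13 = 0.092, RAVLT_imm = -0.174,
    TMT_B = 2.126, DSST = -0.616)
}

adni_slope_interactions <- function() {
  rbind(
    MCI      = c(MMSE = -0.008, ADAS13 = -0.070, RAVLT_imm = 0.064,
                 TMT_B = -1.629, DSST = 0.477),
    Dementia = c(MMSE = -0.002, ADAS13 = -0.076, RAVLT_imm = 0.199,
                 TMT_B = -2.383, DSST = 0.943)
  )
}

# GM/TIV (%) decline per year: CN estimate plus group interactions
adni_atrophy_slopes <- function() {
  c(CN = -0.153, MCI = -0.153 + 0.062, Dementia = -0.153 + 0.106)
}

cohort_age_slopes <- function() {
  cn <- adni_cn_slopes()
  ia <- adni_slope_interactions()
  m <- rbind(CN = cn, MCI = cn + ia["MCI", ], Dementia = cn + ia["Dementia", ])
  colnames(m) <- names(cn)
  m[, tests_in_order(), drop = FALSE]
}

# ---------------------------------------------------------------------------
# Latent feature model: a single gray-matter atrophy axis (GM %TIV) drives
# regional volumes, ventricular expansion, cortical thinning and surface-area
# loss; independent Gaussian measurement noise sits on top.

dk_volume_shares <- function() {
  s <- c(
    bankssts = 0.010, caudalanteriorcingulate = 0.010,
    caudalmiddlefrontal = 0.025, cuneus = 0.020, entorhinal = 0.010,
    frontalpole = 0.005, fusiform = 0.035, inferiorparietal = 0.055,
    inferiortemporal = 0.040, insula = 0.030, isthmuscingulate = 0.010,
    lateraloccipital = 0.045, lateralorbitofrontal = 0.030, lingual = 0.030,
    medialorbitofrontal = 0.020, middletemporal = 0.045, paracentral = 0.015,
    parahippocampal = 0.010, parsopercularis = 0.020, parsorbitalis = 0.010,
    parstriangularis = 0.015, pericalcarine = 0.015, postcentral = 0.040,
    posteriorcingulate = 0.015, precentral = 0.055, precuneus = 0.040,
    rostralanteriorcingulate = 0.010, rostralmiddlefrontal = 0.060,
    superiorfrontal = 0.080, superiorparietal = 0.045,
    superiortemporal = 0.045, supramarginal = 0.040, temporalpole = 0.010,
    transversetemporal = 0.005
  )
  s[dk_regions()] / sum(s)
}

dk_thickness_baselines <- function() {
  t <- setNames(rep(2.4, 34), dk_regions())
  t[c("entorhinal", "temporalpole", "insula", "middletemporal",
      "superiortemporal", "inferiortemporal", "fusiform",
      "parahippocampal")] <- c(3.3, 3.6, 3.0, 2.9, 2.8, 2.8, 2.7, 2.7)
  t[c("postcentral", "pericalcarine", "cuneus", "lingual",
      "lateraloccipital", "precentral", "superiorfrontal")] <-
    c(2.0, 1.6, 1.9, 2.0, 2.2, 2.6, 2.7)
  t
}

# GM shares of the subcortical gray structures (fractions of total GM)
subcortical_gm_shares <- function() {
  c(hippocampus = 0.0125, amygdala = 0.005, putamen = 0.0155,
    caudate = 0.0105, pallidum = 0.005, thalamus = 0.020,
    accumbens = 0.0015)
}

# Per-feature baseline value and sensitivity (loading) to the GM %TIV axis
feature_model <- function(gm_ref = 31) {
  reg <- feature_registry()
  dk <- dk_regions()
  dks <- dk_volume_shares()
  sub <- subcortical_gm_shares()
  kappa <- 1 - sum(sub)            # cortical share of total GM

  baseline <- setNames(numeric(nrow(reg)), reg$feature)
  loading <- baseline

  for (s in names(sub)) {
    loading[paste0("vbm_", s)] <- sub[[s]]
    baseline[paste0("vbm_", s)] <- sub[[s]] * gm_ref
  }
  loading["vbm_cerebral_cortex"] <- kappa
  baseline["vbm_cerebral_cortex"] <- kappa * gm_ref
  loading[paste0("vbm_ctx_", dk)] <- kappa * dks
  baseline[paste0("vbm_ctx_", dk)] <- kappa * dks * gm_ref

  # ventricles expand and white matter shrinks mildly with GM loss
  baseline["vbm_lateral_ventricle"] <- 1.30
  loading["vbm_lateral_ventricle"] <- -0.45
  baseline["vbm_inf_lat_vent"] <- 0.07
  loading["vbm_inf_lat_vent"] <- -0.008
  baseline["vbm_cerebral_white_matter"] <- 29.0
  loading["vbm_cerebral_white_matter"] <- 0.20

  th <- dk_thickness_baselines()
  baseline[paste0("sbm_thick_", dk)] <- th
  loading[paste0("sbm_thick_", dk)] <- 0.03
  baseline[paste0("sbm_area_", dk)] <- dks * 90000
  loading[paste0("sbm_area_", dk)] <- 0.005 * dks * 90000

  tibble::tibble(feature = reg$feature, type = reg$type,
                 baseline = unname(baseline[reg$feature]),
                 loading = unname(loading[reg$feature]))
}

gm_feature_names <- function() {
  c("vbm_cerebral_cortex", paste0("vbm_", names(subcortical_gm_shares())))
}

# ---------------------------------------------------------------------------
# Structure-function weight patterns.  Patterns are expressed per unit SD of
# each feature's deviation and then rescaled so the morphometric signal
# explains `signal_fraction` of the configured score variance.

# name -> feature columns (DK names spill into both volume and thickness)
pattern_to_features <- function(pattern) {
  sub <- aseg_structures()
  out <- numeric(0)
  for (s in names(pattern)) {
    v <- pattern[[s]]
    if (s %in% sub) {
      out[paste0("vbm_", s)] <- v
    } else {
      out[paste0("vbm_ctx_", s)] <- v
      out[paste0("sbm_thick_", s)] <- v / 2
    }
  }
  out
}

base_sfa_patterns <- function() {
  list(
    MMSE = c(cerebral_cortex = 2, hippocampus = 2, accumbens = 1,
             cerebral_white_matter = 1, inf_lat_vent = -1, precuneus = 1.5,
             superiorparietal = 1, parstriangularis = 0.5,
             caudalmiddlefrontal = 0.5, fusiform = 0.5),
    ADAS13 = c(hippocampus = -2, amygdala = -1, putamen = -1,
               entorhinal = -2, inf_lat_vent = 1.5, parahippocampal = -1,
               cerebral_white_matter = -0.5),
    RAVLT_imm = c(hippocampus = 2, entorhinal = 1.5, inferiorparietal = 1,
                  posteriorcingulate = 1, insula = 0.5, inf_lat_vent = -1,
                  amygdala = 0.5),
    TMT_B = c(inferiorparietal = -1.5, supramarginal = -1,
              cerebral_white_matter = -1, entorhinal = -0.5,
              parahippocampal = -0.5, superiorparietal = -0.5),
    DSST = c(caudate = 1, cerebral_cortex = 1, inferiorparietal = 1.5,
             rostralmiddlefrontal = 1, hippocampus = 1, fusiform = 0.5,
             middletemporal = 0.5)
  )
}

# cohort-specific emphasis: normal aging is fronto-parietal, MCI mesial
# temporal, dementia widespread temporo-parietal
cohort_tilt_structures <- function() {
  list(
    CN = c("superiorfrontal", "rostralmiddlefrontal", "superiorparietal",
           "caudate"),
    MCI = c("hippocampus", "entorhinal", "parahippocampal", "amygdala"),
    Dementia = c("middletemporal", "inferiortemporal", "inferiorparietal",
                 "precuneus", "posteriorcingulate")
  )
}

build_weight_vectors <- function(fm, score_sds, signal_fraction, separation,
                                 atrophy_sd, feature_noise_sd) {
  feats <- fm$feature
  noise_sd <- feature_noise_sd * abs(fm$baseline)
  dev_sd <- sqrt((fm$loading * atrophy_sd)^2 + noise_sd^2)
  dir_sign <- setNames(
    ifelse(test_scales()$direction == "higher_better", 1, -1),
    tests_in_order())

  base <- base_sfa_patterns()
  tilts <- cohort_tilt_structures()
  tests <- tests_in_order()

  out <- list()
  for (g in cohort_levels()) {
    W <- matrix(0, nrow = length(tests), ncol = length(feats),
                dimnames = list(tests, feats))
    tilt_pat <- setNames(rep(0.6, length(tilts[[g]])), tilts[[g]])
    for (t in tests) {
      p <- pattern_to_features(base[[t]])
      tl <- pattern_to_features(tilt_pat) * dir_sign[[t]] * separation
      full <- p
      for (f in names(tl)) {
        cur <- if (f %in% names(full)) full[[f]] else 0
        full[f] <- cur + tl[[f]]
      }
      w <- setNames(numeric(length(feats)), feats)
      keep <- names(full)[names(full) %in% feats]
      # per-SD pattern -> raw feature scale
      w[keep] <- full[keep] / pmax(dev_sd[match(keep, feats)], 1e-12)
      sig_var <- (sum(w * fm$loading) * atrophy_sd)^2 + sum((w * noise_sd)^2)
      target <- signal_fraction * score_sds[g, t]^2
      if (sig_var > 0) w <- w * sqrt(target / sig_var)
      W[t, ] <- w
    }
    out[[g]] <- W
  }
  out
}

# ---------------------------------------------------------------------------

#' Configure the three-cohort synthetic data generator
#'
#' Builds a full generative specification of cognitively normal (CN), MCI and
#' dementia cohorts with cohort-specific, planted structure-function
#' associations.  Defaults reproduce the study conditions the package's
#' analytics are designed for:
#'
#' * cohort sizes 287/646/369 and uniform ages on 55-90 years;
#' * per-cohort score means and SDs matching published ADNI1 cohort
#'   descriptive statistics, with MMSE/ADAS13 age trends essentially flat
#'   within cohorts;
#' * DSST and TMT-B cohort trendlines that intersect at
#'   `convergence_age` (100 years), with the CN trendline anchored at the CN
#'   cohort mean and slopes taken from the published within-CN estimates plus
#'   group interactions;
#' * a single latent gray-matter atrophy axis (GM %TIV, declining
#'   cohort-specifically with age) that drives all 45 VBM and 68 SBM
#'   features, plus independent Gaussian measurement noise;
#' * morphometry explains `signal_fraction` of each score's variance through
#'   cohort-specific weight vectors; the remainder is Gaussian residual noise
#'   so that the total variance matches the configured SDs.
#'
#' @param n_per_cohort Named integer vector of cohort sizes (CN, MCI,
#'   Dementia).
#' @param age_range Two-element numeric vector of years; ages are drawn
#'   uniformly.
#' @param convergence_age Age (years) at which the DSST and TMT-B cohort
#'   trendlines intersect.
#' @param signal_fraction Fraction of score variance explained by
#'   morphometry (0-1).
#' @param separation Scalar `delta` scaling the inter-cohort differences of
#'   the structure-function weight vectors; 0 gives identical weights in all
#'   cohorts.
#' @param atrophy_sd Between-subject SD of the latent GM %TIV level at fixed
#'   age.
#' @param feature_noise_sd Measurement noise per feature, as a fraction of
#'   the feature's baseline value.
#' @param seed Integer RNG seed stored in the config; generation is
#'   bit-reproducible given the config.
#' @return An object of class `sfa_sim_config`.
#' @seealso [generate_cohorts()], [null_sim_config()], [scale_noise()]
#' @export
sfa_sim_config <- function(n_per_cohort = c(CN = 287, MCI = 646, Dementia = 369),
                           age_range = c(55, 90),
                           convergence_age = 100,
                           signal_fraction = 0.15,
                           separation = 1,
                           atrophy_sd = 1.5,
                           feature_noise_sd = 0.05,
                           seed = 1L) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            signal_fraction >= 0, signal_fraction < 1,
            separation >= 0, atrophy_sd >= 0, feature_noise_sd >= 0)
  n_per_cohort <- n_per_cohort[cohort_levels()]
  if (any(is.na(n_per_cohort)) || any(n_per_cohort < 0)) {
    stop("`n_per_cohort` must name non-negative CN, MCI and Dementia counts",
         call. = FALSE)
  }
  age_mid <- mean(age_range)
  tests <- tests_in_order()
  means <- adni_score_means()
  sds <- adni_score_sds()
  slopes <- cohort_age_slopes()

  # Intercepts (cohort mean at mid-age).  MMSE/ADAS13/RAVLT use the cohort
  # means directly; for the converging DSST/TMT trendlines the CN line is
  # anchored at the CN mean and the MCI/Dementia intercepts are derived from
  # the common intersection point at `convergence_age`.
  intercepts <- means
  span <- convergence_age - age_mid
  for (t in c("TMT_B", "DSST")) {
    v_conv <- means["CN", t] + slopes["CN", t] * span
    for (g in c("MCI", "Dementia")) {
      intercepts[g, t] <- v_conv - slopes[g, t] * span
    }
  }

  gm_conv <- 28                       # GM %TIV common point at convergence
  atro <- adni_atrophy_slopes()
  gm_baselines <- gm_conv - atro * span

  score_noise_sd <- sqrt(1 - signal_fraction) * sds

  fm <- feature_model()
  weights <- build_weight_vectors(fm, sds, signal_fraction, separation,
                                  atrophy_sd, feature_noise_sd)

  structure(list(
    n_per_cohort = n_per_cohort,
    age_range = age_range,
    age_mid = age_mid,
    convergence_age = convergence_age,
    score_intercepts = intercepts,
    score_sds = sds,
    age_slopes = slopes,
    score_noise_sd = score_noise_sd,
    signal_fraction = signal_fraction,
    separation = separation,
    atrophy_slopes = atro,
    gm_baselines = gm_baselines,
    gm_ref = 31,
    atrophy_sd = atrophy_sd,
    feature_noise_sd = feature_noise_sd,
    weight_vectors = weights,
    sex_prob_f = c(CN = 0.4669, MCI = 0.3328, Dementia = 0.4688),
    edu_mean = c(CN = 16.13, MCI = 15.76, Dementia = 14.85),
    edu_sd = c(CN = 2.91, MCI = 2.99, Dementia = 3.21),
    seed = as.integer(seed)
  ), class = "sfa_sim_config")
}

#' Default generator configuration
#'
#' @inheritParams sfa_sim_config
#' @return An `sfa_sim_config` with all defaults.
#' @export
default_sim_config <- function(seed = 1L) sfa_sim_config(seed = seed)

#' Exchangeable-cohorts null configuration
#'
#' All three cohorts share the CN score distributions, age trends, atrophy
#' dynamics and structure-function weights, and `separation = 0`, so cohort
#' labels carry no information.  Used to calibrate the classifier against
#' chance.
#'
#' @inheritParams sfa_sim_config
#' @return An `sfa_sim_config`.
#' @export
null_sim_config <- function(n_per_cohort = c(CN = 300, MCI = 300, Dementia = 300),
                            seed = 1L) {
  cfg <- sfa_sim_config(n_per_cohort = n_per_cohort, separation = 0,
                        seed = seed)
  for (nm in c("score_intercepts", "score_sds", "age_slopes",
               "score_noise_sd")) {
    cfg[[nm]][] <- rep(cfg[[nm]]["CN", ], each = 3)
  }
  cfg$atrophy_slopes[] <- cfg$atrophy_slopes[["CN"]]
  cfg$gm_baselines[] <- cfg$gm_baselines[["CN"]]
  cfg$sex_prob_f[] <- cfg$sex_prob_f[["CN"]]
  cfg$edu_mean[] <- cfg$edu_mean[["CN"]]
  cfg$edu_sd[] <- cfg$edu_sd[["CN"]]
  cfg$weight_vectors$MCI <- cfg$weight_vectors$CN
  cfg$weight_vectors$Dementia <- cfg$weight_vectors$CN
  cfg
}

#' Rescale all noise sources of a generator configuration
#'
#' Multiplies the score residual SDs, the feature measurement noise and the
#' between-subject atrophy SD by `factor`; `factor = 0` gives the noise-free
#' deterministic limit.  Weight vectors are left untouched.
#'
#' @param config An `sfa_sim_config`.
#' @param factor Non-negative scalar.
#' @return The modified config.
#' @export
scale_noise <- function(config, factor) {
  stopifnot(inherits(config, "sfa_sim_config"), factor >= 0)
  config$score_noise_sd <- config$score_noise_sd * factor
  config$feature_noise_sd <- config$feature_noise_sd * factor
  config$atrophy_sd <- config$atrophy_sd * factor
  config
}

#' @export
print.sfa_sim_config <- function(x, ...) {
  cat("<sfa_sim_config>\n")
  cat("  cohorts:", paste(sprintf("%s=%d", names(x$n_per_cohort),
                                  x$n_per_cohort), collapse = ", "), "\n")
  cat("  ages:", x$age_range[1], "-", x$age_range[2],
      " convergence:", x$convergence_age, "y\n")
  cat("  signal fraction:", x$signal_fraction,
      " separation:", x$separation, " seed:", x$seed, "\n")
  invisible(x)
}

# latent pre-clip mean such that the clipped score mean (averaged over the
# uniform age distribution) equals the configured cohort mean
solve_latent_mean <- function(target, slope, s_total, lo, hi, age_range,
                              age_mid) {
  ages <- seq(age_range[1], age_range[2], length.out = 41)
  g <- function(mu) {
    mean(vapply(mu + slope * (ages - age_mid),
                clipped_normal_mean, numeric(1),
                sd = s_total, lo = lo, hi = hi)) - target
  }
  drift <- abs(slope) * diff(age_range)
  lower <- target - 8 * (s_total + 1) - drift
  upper <- target + 8 * (s_total + 1) + drift
  if (g(lower) > 0 || g(upper) < 0) return(target)  # unclippable target
  uniroot(g, c(lower, upper), tol = 1e-8)$root
}

#' Generate synthetic three-cohort datasets
#'
#' Draws subjects according to an [sfa_sim_config()]: ages are uniform; a
#' latent gray-matter level follows the cohort's age trend plus Gaussian
#' between-subject variation; all morphometric features derive from that
#' latent level plus measurement noise; each test score is the cohort
#' intercept plus its age trend plus the cohort's weight vector applied to
#' the subject's *age-detrended* feature deviations plus residual noise,
#' clipped to the nominal scale bounds.  The latent pre-clip mean is solved
#' so that the clipped cohort mean matches the configured intercept.
#'
#' The generating (pre-residual-noise, unclipped) scores and cohort labels
#' are stored alongside the data and recoverable with [planted_truth()].
#'
#' @param config An `sfa_sim_config`.
#' @return A tibble with one row per subject: `subject_id`, `visit_index`,
#'   `age`, `sex`, `education`, `cohort`, the five test scores, `GM_TIV`
#'   (observed gray-matter %TIV) and the 113 `vbm_*`/`sbm_*` features.
#' @export
#' @examples
#' d <- generate_cohorts(sfa_sim_config(n_per_cohort = c(CN = 20, MCI = 20,
#'                                                       Dementia = 20)))
#' dplyr::count(d, cohort)
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sfa_sim_config"))
  num_fields <- c("score_intercepts", "score_sds", "age_slopes",
                  "score_noise_sd", "atrophy_slopes", "gm_baselines")
  for (nm in num_fields) {
    if (!all(is.finite(config[[nm]]))) {
      stop("non-finite values in config field `", nm, "`", call. = FALSE)
    }
  }
  fm <- feature_model(config$gm_ref)
  feats <- fm$feature
  noise_sd <- config$feature_noise_sd * abs(fm$baseline)
  tests <- tests_in_order()
  sc <- test_scales()
  set.seed(config$seed)

  rows <- list()
  truth_rows <- list()
  for (g in cohort_levels()) {
    n <- config$n_per_cohort[[g]]
    if (n == 0) next
    age <- runif(n, config$age_range[1], config$age_range[2])
    adev <- rnorm(n, 0, config$atrophy_sd)
    gm_det <- config$gm_baselines[[g]] +
      config$atrophy_slopes[[g]] * (age - config$age_mid)
    eps <- matrix(rnorm(n * length(feats)), n) %*% diag(noise_sd)
    fdev <- outer(adev, fm$loading) + eps      # deviation from age-expected
    fdet <- outer(gm_det - config$gm_ref, fm$loading) +
      matrix(fm$baseline, n, length(feats), byrow = TRUE)
    ffull <- pmax(fdet + fdev, 0)
    colnames(ffull) <- feats

    W <- config$weight_vectors[[g]]
    signal <- fdev %*% t(W[tests, feats, drop = FALSE])

    sex <- factor(ifelse(runif(n) < config$sex_prob_f[[g]], "F", "M"),
                  levels = c("F", "M"))
    edu <- clip_to(rnorm(n, config$edu_mean[[g]], config$edu_sd[[g]]), 6, 20)

    scores <- matrix(NA_real_, n, length(tests),
                     dimnames = list(NULL, tests))
    truths <- scores
    for (t in tests) {
      i <- match(t, sc$name)
      sig_sd <- sd_of_signal(config, g, t, fm, noise_sd)
      s_tot <- sqrt(sig_sd^2 + config$score_noise_sd[g, t]^2)
      mu <- solve_latent_mean(config$score_intercepts[g, t],
                              config$age_slopes[g, t], s_tot,
                              sc$min_score[i], sc$max_score[i],
                              config$age_range, config$age_mid)
      det <- mu + config$age_slopes[g, t] * (age - config$age_mid)
      tru <- det + signal[, t]
      obs <- clip_to(tru + rnorm(n, 0, config$score_noise_sd[g, t]),
                     sc$min_score[i], sc$max_score[i])
      truths[, t] <- tru
      scores[, t] <- obs
    }

    id <- sprintf("SYN%d-%s-%04d", config$seed, g, seq_len(n))
    base <- tibble::tibble(subject_id = id, visit_index = 1L, age = age,
                           sex = sex, education = edu,
                           cohort = factor(g, levels = cohort_levels()))
    base <- dplyr::bind_cols(base, tibble::as_tibble(scores))
    base$GM_TIV <- rowSums(ffull[, gm_feature_names(), drop = FALSE])
    rows[[g]] <- dplyr::bind_cols(base, tibble::as_tibble(ffull))
    truth_rows[[g]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = id,
                     cohort = factor(g, levels = cohort_levels())),
      tibble::as_tibble(truths))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "sfa_provenance") <- "synthetic"
  attr(out, "sfa_config") <- config
  attr(out, "sfa_truth") <- dplyr::bind_rows(truth_rows)
  out
}

# SD of the planted morphometric signal for one (cohort, test)
sd_of_signal <- function(config, cohort, test, fm = feature_model(config$gm_ref),
                         noise_sd = config$feature_noise_sd * abs(fm$baseline)) {
  w <- config$weight_vectors[[cohort]][test, fm$feature]
  sqrt((sum(w * fm$loading) * config$atrophy_sd)^2 + sum((w * noise_sd)^2))
}

#' Recover the planted ground truth of a synthetic dataset
#'
#' @param data A dataset produced by [generate_cohorts()].
#' @return A tibble with `subject_id`, the generating `cohort`, and the
#'   noise-free (pre-residual-noise, unclipped) value of each test score.
#' @export
planted_truth <- function(data) {
  if (!identical(attr(data, "sfa_provenance"), "synthetic") ||
      is.null(attr(data, "sfa_truth"))) {
    stop("planted truth is only available for datasets built by ",
         "`generate_cohorts()`", call. = FALSE)
  }
  attr(data, "sfa_truth")
}
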