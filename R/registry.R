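#' Cognitive test battery metadata
#'
#' Scale floors, ceilings and scoring direction for the five tests the
#' screening models operate on: the Mini-Mental State Examination (MMSE,
#' 0-30 points, higher is better), the 13-item Alzheimer's Disease Assessment
#' Scale cognitive subscale (ADAS13, 0-85 points, higher is worse), the Rey
#' Auditory Verbal Learning Test immediate-recall total (RAVLT_imm, 0-75
#' words), part B of the Trail Making Test (TMT_B, completion time in
#' seconds, capped at 300 at administration), and the Digit Symbol
#' Substitution Test (DSST, 0-93 correct substitutions).
#'
#' The nominal bounds are used to validate incoming scores and to clip
#' synthetic draws; prediction-error normalisation uses the *empirical*
#' pooled range by default (see [empirical_range()]), because observed ADNI
#' score ranges are substantially narrower than the nominal scales.
#'
#' @return A tibble with columns `name`, `min_score`, `max_score`,
#'   `direction` (`"higher_better"` or `"lower_better"`).
#' @export
#' @examples
#' test_scales()
test_scales <- function() {
  tibble::tibble(
    name       = c("MMSE", "ADAS13", "RAVLT_imm", "TMT_B", "DSST"),
    min_score  = c(0, 0, 0, 0, 0),
    max_score  = c(30, 85, 75, 300, 93),
    direction  = c("higher_better", "lower_better", "higher_better",
                   "lower_better", "higher_better")
  )
}

#' Desikan-Killiany cortical parcellation regions
#'
#' The 34 cortical regions per hemisphere of the Desikan-Killiany atlas, in
#' FreeSurfer's `?h.aparc.stats` spelling.
#'
#' @return Character vector of length 34.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

# aseg-derived global/subcortical structures kept as VBM predictors
aseg_structures <- function() {
  c("hippocampus", "amygdala", "putamen", "caudate", "pallidum",
    "thalamus", "accumbens", "lateral_ventricle", "inf_lat_vent",
    "cerebral_white_matter", "cerebral_cortex")
}

#' Morphometric feature registry
#'
#' Canonical names of the 113 structural predictors used throughout the
#' package: 45 voxel-based morphometry (VBM) features (11 global/subcortical
#' relative volumes from FreeSurfer's `aseg.stats` plus 34 Desikan-Killiany
#' cortical parcellation volumes, all expressed as percent of total
#' intracranial volume) and 68 surface-based morphometry (SBM) features
#' (mean cortical thickness in mm and total surface area in mm^2 per DK
#' region, averaged over hemispheres).
#'
#' @return A tibble with columns `feature` (column name used in datasets),
#'   `type` (`"VBM"` or `"SBM"`), and `structure` (anatomical name).
#' @export
feature_registry <- function() {
  dk <- dk_regions()
  sub <- aseg_structures()
  tibble::tibble(
    feature = c(paste0("vbm_", sub), paste0("vbm_ctx_", dk),
                paste0("sbm_thick_", dk), paste0("sbm_area_", dk)),
    type = c(rep("VBM", length(sub) + length(dk)),
             rep("SBM", 2L * length(dk))),
    structure = c(sub, dk, dk, dk)
  )
}

#' Select feature columns of a dataset
#'
#' @param data A subject-level tibble whose morphometric columns follow the
#'   `vbm_*` / `sbm_*` naming of [feature_registry()].
#' @param feature_set `"VBM"`, `"SBM"` or `"VBM+SBM"`.
#' @return Character vector of column names present in `data`.
#' @export
feature_columns <- function(data, feature_set = "VBM+SBM") {
  feature_set <- match.arg(feature_set, c("VBM", "SBM", "VBM+SBM"))
  nm <- names(data)
  vbm <- nm[startsWith(nm, "vbm_")]
  sbm <- nm[startsWith(nm, "sbm_")]
  switch(feature_set, VBM = vbm, SBM = sbm, `VBM+SBM` = c(vbm, sbm))
}
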