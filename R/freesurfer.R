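# Readers for the FreeSurfer stats dialect (aseg.stats, ?h.aparc.stats):
# '#'-prefixed comment headers carrying 'Measure' summary lines, a
# '# ColHeaders' line naming the whitespace-delimited body columns.

read_stats_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ch <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  if (length(ch) == 0) {
    stop("parse error: no ColHeaders line in ", path, call. = FALSE)
  }
  headers <- strsplit(sub("^#\\s*ColHeaders\\s+", "", ch[1]), "\\s+")[[1]]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    stop("parse error: no body rows in ", path, call. = FALSE)
  }
  df <- utils::read.table(text = body, col.names = headers,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

read_measure <- function(path, measure) {
  lines <- readLines(path, warn = FALSE)
  m <- grep(paste0("^#\\s*Measure\\s+", measure, ","), lines, value = TRUE)
  if (length(m) == 0) return(NA_real_)
  parts <- trimws(strsplit(m[1], ",")[[1]])
  suppressWarnings(as.numeric(parts[length(parts) - 1]))
}

#' Parse FreeSurfer stats files into absolute volumes
#'
#' Reads an `aseg.stats` file plus the left/right `?h.aparc.stats`
#' (Desikan-Killiany) files and returns absolute volumes in mm^3, per
#' structure and hemisphere, together with the estimated total intracranial
#' volume (TIV).
#'
#' @param aseg_path Path to `aseg.stats`; must carry the
#'   `Measure EstimatedTotalIntraCranialVol` line.
#' @param aparc_lh_path,aparc_rh_path Paths to `lh.aparc.stats` and
#'   `rh.aparc.stats`.
#' @return An object of class `fs_volumes`: `tiv` (mm^3), `aseg` (tibble
#'   `structure`, `volume`), `aparc` (tibble `hemi`, `region`, `gray_vol`,
#'   `thick_avg`, `surf_area`).
#' @seealso [compute_relative_volumes()]
#' @export
parse_freesurfer_stats <- function(aseg_path, aparc_lh_path, aparc_rh_path) {
  for (p in c(aseg_path, aparc_lh_path, aparc_rh_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  tiv <- read_measure(aseg_path, "EstimatedTotalIntraCranialVol")
  if (is.na(tiv)) {
    stop("parse error: no EstimatedTotalIntraCranialVol measure in ",
         aseg_path, call. = FALSE)
  }
  aseg <- read_stats_body(aseg_path)
  if (!all(c("StructName", "Volume_mm3") %in% names(aseg))) {
    stop("parse error: aseg body lacks StructName/Volume_mm3 columns",
         call. = FALSE)
  }
  read_aparc <- function(path, hemi) {
    b <- read_stats_body(path)
    if (!all(c("StructName", "GrayVol") %in% names(b))) {
      stop("parse error: aparc body lacks StructName/GrayVol columns",
           call. = FALSE)
    }
    tibble::tibble(hemi = hemi, region = b$StructName,
                   gray_vol = b$GrayVol,
                   thick_avg = if ("ThickAvg" %in% names(b)) b$ThickAvg else NA_real_,
                   surf_area = if ("SurfArea" %in% names(b)) b$SurfArea else NA_real_)
  }
  structure(list(
    tiv = tiv,
    aseg = tibble::tibble(structure = aseg$StructName,
                          volume = aseg$Volume_mm3),
    aparc = dplyr::bind_rows(read_aparc(aparc_lh_path, "lh"),
                             read_aparc(aparc_rh_path, "rh"))
  ), class = "fs_volumes")
}

canon_structure <- function(x) gsub("-", "_", tolower(x))

#' Convert absolute volumes to relative (% of TIV) features
#'
#' Bilateral structures are averaged over hemispheres, then every volume is
#' expressed as a percentage of total intracranial volume:
#' `100 * ((left + right) / 2) / TIV`.  Midline/unpaired structures use
#' their single volume.  Cortical parcellation volumes are returned under
#' `ctx_<region>` names.
#'
#' @param raw An `fs_volumes` object from [parse_freesurfer_stats()].
#' @return A tibble with `structure` and `value` (% of TIV).  A structure
#'   measured in only one hemisphere yields `NA` with a warning.
#' @export
compute_relative_volumes <- function(raw) {
  stopifnot(inherits(raw, "fs_volumes"))
  if (!is.finite(raw$tiv) || raw$tiv <= 0) {
    stop("domain error: TIV must be positive (got ", raw$tiv, ")",
         call. = FALSE)
  }
  aseg <- raw$aseg
  side <- dplyr::case_when(
    grepl("^Left-", aseg$structure) ~ "left",
    grepl("^Right-", aseg$structure) ~ "right",
    TRUE ~ "none"
  )
  base <- sub("^(Left|Right)-", "", aseg$structure)

  lateral <- side != "none"
  paired <- tibble::tibble(base = base[lateral],
                           side = side[lateral],
                           volume = aseg$volume[lateral]) |>
    dplyr::summarise(
      value = if (dplyr::n_distinct(.data$side) == 2) {
        100 * mean(.data$volume) / raw$tiv
      } else {
        NA_real_
      },
      .by = "base")
  if (any(is.na(paired$value))) {
    warning("structure(s) present in one hemisphere only: ",
            paste(paired$base[is.na(paired$value)], collapse = ", "),
            call. = FALSE)
  }

  unpaired <- tibble::tibble(base = base[side == "none"],
                             value = 100 * aseg$volume[side == "none"] /
                               raw$tiv)

  ctx <- raw$aparc |>
    dplyr::summarise(
      value = if (dplyr::n() == 2) 100 * mean(.data$gray_vol) / raw$tiv
              else NA_real_,
      .by = "region")
  if (any(is.na(ctx$value))) {
    warning("cortical region(s) present in one hemisphere only: ",
            paste(ctx$region[is.na(ctx$value)], collapse = ", "),
            call. = FALSE)
  }

  dplyr::bind_rows(
    tibble::tibble(structure = canon_structure(paired$base),
                   value = paired$value),
    tibble::tibble(structure = canon_structure(unpaired$base),
                   value = unpaired$value),
    tibble::tibble(structure = paste0("ctx_", canon_structure(ctx$region)),
                   value = ctx$value)
  )
}
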