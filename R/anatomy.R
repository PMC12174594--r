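#' Pixel geometry of a B-scan
#'
#' Converts pixel counts to physical units. The default lateral pitch follows
#' a 9-mm scan sampled at 1,024 columns; the axial pitch defaults to 1 so all
#' thicknesses are reported in pixel units unless a device calibration is
#' supplied. Area conversion is opt-in: measurement functions report pixel
#' counts unless given a geometry (the trend framework is relative and
#' therefore unit-free).
#'
#' @param lateral_um_per_px micrometres per pixel laterally (> 0).
#' @param axial_um_per_px micrometres per pixel axially (> 0).
#' @return An object of class `pixel_geometry`.
#' @export
pixel_geometry <- function(lateral_um_per_px = 9000 / 1024,
                           axial_um_per_px = 1) {
  if (lateral_um_per_px <= 0 || axial_um_per_px <= 0)
    stopf("pixel pitches must be strictly positive")
  structure(list(lateral_um_per_px = lateral_um_per_px,
                 axial_um_per_px = axial_um_per_px),
            class = "pixel_geometry")
}

check_mask_labels <- function(mask, what = "mask") {
  if (!all(mask %in% c(0L, 1L, 2L)))
    stopf("%s labels must be in {0, 1, 2}", what)
}

#' Per-column retinal thickness profile
#'
#' Retinal thickness is the per-column count of class-1 (ILM-to-RPE) pixels,
#' scaled by the axial pixel pitch. Columns containing no retina return 0; an
#' entirely empty mask additionally raises a warning.
#'
#' @param strat_mask integer matrix with labels 0 (background), 1 (ILM to RPE
#'   upper limit), 2 (RPE upper limit to choroid lower limit).
#' @param geometry a [pixel_geometry()]; `NULL` means pixel units.
#' @return Numeric vector of length `ncol(strat_mask)`.
#' @export
thickness_profile <- function(strat_mask, geometry = NULL) {
  check_mask_labels(strat_mask, "strat_mask")
  axial <- if (is.null(geometry)) 1 else geometry$axial_um_per_px
  prof <- colSums(strat_mask == 1L) * axial
  if (all(prof == 0))
    warning("stratification mask contains no retina (class 1)", call. = FALSE)
  prof
}

fovea_column <- function(fovea_x, width) {
  if (!is.numeric(fovea_x) || is.na(fovea_x) || fovea_x < 0 || fovea_x > 1)
    stopf("fovea_x must lie in [0, 1], got %s", format(fovea_x))
  round_half_away(fovea_x * (width - 1L)) + 1L
}

#' Central retinal thickness (CRT)
#'
#' Thickness of the class-1 band at the foveal column,
#' `round(fovea_x * (width - 1))` with half rounded away from zero.
#'
#' @inheritParams thickness_profile
#' @param fovea_x normalized foveal abscissa in \[0, 1\].
#' @return CRT in axial units (pixels by default).
#' @export
central_retinal_thickness <- function(strat_mask, fovea_x, geometry = NULL) {
  col <- fovea_column(fovea_x, ncol(strat_mask))
  prof <- suppressWarnings(thickness_profile(strat_mask, geometry))
  prof[col]
}

#' Maximal retinal thickness within one B-scan
#'
#' @inheritParams thickness_profile
#' @return Maximum of the thickness profile (0, with a warning, for an empty
#'   mask).
#' @export
maximal_retinal_thickness <- function(strat_mask, geometry = NULL) {
  max(thickness_profile(strat_mask, geometry))
}

#' Fluid lesion areas
#'
#' Counts SRF (label 1) and IRC (label 2) pixels in a lesion mask. Areas are
#' pixel counts unless a [pixel_geometry()] is supplied, in which case they
#' are converted to square micrometres.
#'
#' @param lesion_mask integer matrix with labels 0 (background), 1 (SRF),
#'   2 (IRC).
#' @param geometry `NULL` (pixel counts) or a [pixel_geometry()].
#' @return Named numeric vector `c(srf_area, irc_area)`.
#' @export
lesion_areas <- function(lesion_mask, geometry = NULL) {
  check_mask_labels(lesion_mask, "lesion_mask")
  factor <- if (is.null(geometry)) 1
            else geometry$lateral_um_per_px * geometry$axial_um_per_px
  c(srf_area = sum(lesion_mask == 1L) * factor,
    irc_area = sum(lesion_mask == 2L) * factor)
}

#' All four anatomical quantities for one scan
#'
#' @inheritParams thickness_profile
#' @inheritParams lesion_areas
#' @param fovea_x normalized foveal abscissa.
#' @return An `anatomy_measurements` list with `crt`, `max_thickness`,
#'   `srf_area`, `irc_area`.
#' @export
anatomy_measurements <- function(strat_mask, lesion_mask, fovea_x,
                                 geometry = NULL) {
  prof <- suppressWarnings(thickness_profile(strat_mask, geometry))
  areas <- lesion_areas(lesion_mask,
                        if (is.null(geometry)) NULL else geometry)
  structure(list(
    crt = prof[fovea_column(fovea_x, ncol(strat_mask))],
    max_thickness = max(prof),
    srf_area = unname(areas["srf_area"]),
    irc_area = unname(areas["irc_area"])
  ), class = "anatomy_measurements")
}

#' Fovea localization error
#'
#' Absolute difference between a predicted and a gold-standard normalized
#' foveal abscissa.
#'
#' @param pred_x,gold_x normalized abscissae in \[0, 1\] (vectorized).
#' @return `|pred_x - gold_x|`.
#' @export
fovea_displacement <- function(pred_x, gold_x) {
  if (any(!is.finite(pred_x)) || any(!is.finite(gold_x)) ||
        any(pred_x < 0 | pred_x > 1) || any(gold_x < 0 | gold_x > 1))
    stopf("fovea abscissae must be finite and in [0, 1]")
  abs(pred_x - gold_x)
}

#' Aggregate fovea localization performance
#'
#' Mean and sd of the displacement plus the fraction of scans whose
#' displacement does not exceed a tolerance (the "accuracy" of macular
#' detection). The tolerance defaults to 0.02 of the image width and is fully
#' configurable since no canonical threshold exists.
#'
#' @inheritParams fovea_displacement
#' @param tol accuracy tolerance on the normalized displacement.
#' @return List with `mean`, `sd`, `accuracy`, `n`.
#' @export
fovea_accuracy <- function(pred_x, gold_x, tol = 0.02) {
  d <- fovea_displacement(pred_x, gold_x)
  list(mean = mean(d), sd = stats::sd(d),
       accuracy = mean(d <= tol), n = length(d))
}

#' Automated structural-continuity quality flags
#'
#' Scans the columns inside the retina's horizontal support for runs of at
#' least `min_gap_columns` columns missing class 1 (neuroepithelium
#' discontinuity), missing class 2 (RPE/choroid band discontinuity), or
#' missing both (entire retinal discontinuity). Such abrupt ruptures are the
#' failure modes that disqualify a predicted B-scan from clinical
#' interpretation.
#'
#' @inheritParams thickness_profile
#' @param min_gap_columns minimum run length (columns) that counts as a
#'   discontinuity.
#' @return An object of class `quality_flags`: logicals
#'   `neuroepithelium_discontinuity`, `rpe_discontinuity`,
#'   `entire_discontinuity`, and `gap_columns`, a data frame of 0-based
#'   inclusive column ranges per defect type.
#' @export
continuity_flags <- function(strat_mask, min_gap_columns = 3L) {
  check_mask_labels(strat_mask, "strat_mask")
  if (min_gap_columns < 1L) stopf("min_gap_columns must be >= 1")
  has1 <- colSums(strat_mask == 1L) > 0L
  has2 <- colSums(strat_mask == 2L) > 0L
  support <- which(has1 | has2)
  gaps <- data.frame(type = character(), start = integer(), end = integer())
  if (length(support) > 0L) {
    lo <- min(support); hi <- max(support)
    find_runs <- function(missing, type) {
      r <- rle(missing[lo:hi])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_gap_columns
      if (!any(keep)) return(NULL)
      data.frame(type = type,
                 start = lo + starts[keep] - 1L - 1L,  # to 0-based
                 end = lo + ends[keep] - 1L - 1L)
    }
    gaps <- rbind(
      find_runs(!has1, "neuroepithelium"),
      find_runs(!has2, "rpe"),
      find_runs(!(has1 | has2), "entire")
    )
    if (is.null(gaps))
      gaps <- data.frame(type = character(), start = integer(),
                         end = integer())
  }
  structure(list(
    neuroepithelium_discontinuity = any(gaps$type == "neuroepithelium"),
    rpe_discontinuity = any(gaps$type == "rpe"),
    entire_discontinuity = any(gaps$type == "entire"),
    gap_columns = gaps
  ), class = "quality_flags")
}

#' @export
print.quality_flags <- function(x, ...) {
  cat("<quality_flags>",
      if (x$entire_discontinuity) "ENTIRE"
      else if (x$neuroepithelium_discontinuity || x$rpe_discontinuity)
        paste(c(if (x$neuroepithelium_discontinuity) "neuroepithelium",
                if (x$rpe_discontinuity) "RPE"), collapse = "+")
      else "intact", "\n")
  if (nrow(x$gap_columns)) print(x$gap_columns)
  invisible(x)
}
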