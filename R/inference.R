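#' Configuration of the classical segmentation backend
#'
#' The backend recovers layer boundaries and fluid from phantom intensity
#' images without any training, playing the role of the measurement
#' instruments (stratification, lesion, and macular-detection models) in the
#' evaluation chain. Its thresholds are calibrated to the phantom renderer's
#' default class reflectivities (see [oct_reflectivity()]); a trained backend
#' can be plugged in instead wherever a stratification/lesion mask is
#' accepted.
#'
#' @param smoothing_window odd number of columns for median smoothing of the
#'   traced boundary curves.
#' @param gradient_threshold axial intensity gradient (per pixel, on the
#'   \[0, 1\] scale) that counts as a layer edge.
#' @param fluid_threshold intensity below which a class-1 pixel is a fluid
#'   candidate.
#' @param min_component_px connected fluid components smaller than this are
#'   discarded.
#' @param class2_level,class2_tol intensity window `level +- tol` treated as
#'   RPE-to-choroid tissue when locating the RPE by change-point fit.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(smoothing_window = 9L,
                             gradient_threshold = 0.04,
                             fluid_threshold = 0.30,
                             min_component_px = 8L,
                             class2_level = 0.35,
                             class2_tol = 0.10) {
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stopf("smoothing_window must be odd and >= 1")
  if (gradient_threshold <= 0 || gradient_threshold >= 1 ||
        fluid_threshold <= 0 || fluid_threshold >= 1)
    stopf("thresholds must lie in (0, 1)")
  if (min_component_px < 1L) stopf("min_component_px must be >= 1")
  structure(list(smoothing_window = smoothing_window,
                 gradient_threshold = gradient_threshold,
                 fluid_threshold = fluid_threshold,
                 min_component_px = as.integer(min_component_px),
                 class2_level = class2_level, class2_tol = class2_tol),
            class = "inference_config")
}

#' Trace retinal layer boundaries from an intensity image
#'
#' Column-wise boundary tracing on a lightly box-blurred image: the ILM is the
#' first strong dark-to-bright axial gradient, the choroid lower limit is one
#' below the last strong bright-to-dark gradient, and the RPE upper limit is
#' placed by an exact change-point fit that best separates class-2-like
#' intensities (below) from retina/fluid intensities (above). The three curves
#' are median-smoothed laterally and rasterized into a stratification mask
#' with the usual class 0/1/2 convention. Columns without detectable retina
#' are labeled background.
#'
#' @param image numeric matrix with intensities in \[0, 1\].
#' @param config an [inference_config()].
#' @return Integer stratification mask, same dimensions as `image`.
#' @export
trace_layer_boundaries <- function(image, config = inference_config()) {
  if (any(image < 0 | image > 1)) stopf("image intensities must lie in [0, 1]")
  H <- nrow(image); W <- ncol(image)
  sm <- box_blur(image, 3L, 3L)
  thr <- config$gradient_threshold
  lo2 <- config$class2_level - config$class2_tol
  hi2 <- config$class2_level + config$class2_tol

  # the blur spreads each step edge over a short run of strong gradients; the
  # middle of the run sits on the true boundary row
  run_mid <- function(idx, first = TRUE) {
    grp <- cumsum(c(1L, diff(idx) != 1L))
    run <- idx[grp == if (first) 1L else grp[length(grp)]]
    run[ceiling(length(run) / 2)]
  }
  ilm <- rep(NA_integer_, W); rpe <- ilm; cho <- ilm
  for (j in seq_len(W)) {
    v <- sm[, j]
    g <- c(0, (v[-1] - v[-H]))          # g[r] = v[r] - v[r-1]
    rising <- which(g > thr)
    falling <- which(g < -thr)
    if (length(rising) == 0L || length(falling) == 0L) next
    ilm0 <- run_mid(rising, first = TRUE) - 1L    # 0-based ILM upper limit
    cho0 <- run_mid(falling, first = FALSE) - 1L  # 0-based choroid lower limit
    if (cho0 - ilm0 < 3L) next
    # change-point over the tissue rows: split so that rows above it are least
    # class-2-like and rows below it most class-2-like
    rows <- (ilm0 + 1L):cho0            # 1-based tissue rows
    like2 <- as.integer(v[rows] >= lo2 & v[rows] <= hi2)
    above <- cumsum(c(0L, like2))                  # class-2-like above split
    below <- sum(1L - like2) - cumsum(c(0L, 1L - like2))
    misfit <- above + below                        # split before rows[k]
    k <- which.min(misfit)
    rpe0 <- if (k > length(rows)) cho0 else rows[k] - 1L
    ilm[j] <- ilm0
    rpe[j] <- min(max(rpe0, ilm0 + 1L), cho0)
    cho[j] <- cho0
  }
  ok <- !is.na(ilm)
  if (!any(ok)) return(matrix(0L, H, W))
  smooth_curve <- function(cv) {
    out <- cv
    out[ok] <- round_half_away(stats::runmed(cv[ok], config$smoothing_window))
    out
  }
  ilm <- smooth_curve(ilm); rpe <- smooth_curve(rpe); cho <- smooth_curve(cho)
  ilm2 <- ifelse(ok, pmin(pmax(ilm, 0L), H - 3L), 0L)
  rpe2 <- ifelse(ok, pmin(pmax(rpe, ilm2 + 1L), H - 2L), 0L)
  cho2 <- ifelse(ok, pmin(pmax(cho, rpe2), H - 1L), 0L)
  rasterize_strat(ilm2, rpe2, cho2, W, H)
}

#' Detect the fovea from a stratification mask
#'
#' The fovea is the abscissa of the minimum of the median-smoothed thickness
#' profile within a central search band; ties are broken toward the image
#' center. Returns `NA` with a warning when the band contains no retina.
#'
#' @param strat_mask integer stratification mask.
#' @param search_band normalized `c(lo, hi)` sub-interval of \[0, 1\] to
#'   search (default the central third).
#' @return Normalized fovea abscissa, or `NA_real_` on failure.
#' @export
detect_fovea <- function(strat_mask, search_band = c(1 / 3, 2 / 3)) {
  if (length(search_band) != 2L || any(search_band < 0 | search_band > 1) ||
        search_band[1L] > search_band[2L])
    stopf("search_band must be an ordered sub-interval of [0, 1]")
  W <- ncol(strat_mask)
  prof <- suppressWarnings(thickness_profile(strat_mask))
  sm <- stats::runmed(prof, min(11L, (W %/% 2L) * 2L - 1L))
  lo <- floor(search_band[1L] * (W - 1L)) + 1L
  hi <- ceiling(search_band[2L] * (W - 1L)) + 1L
  band <- lo:hi
  vals <- sm[band]
  if (all(prof[band] == 0)) {
    warning("no retina inside the fovea search band", call. = FALSE)
    return(NA_real_)
  }
  cand <- band[vals == min(vals)]
  center <- (W + 1) / 2
  col <- cand[which.min(abs(cand - center))]
  (col - 1L) / (W - 1L)
}

#' Segment fluid lesions from an intensity image
#'
#' Hypo-reflective pixels inside the class-1 band form candidate components;
#' components smaller than `min_component_px` are discarded. A component
#' touching the RPE upper boundary is subretinal fluid (label 1); interior
#' components are intraretinal cysts (label 2) — the anatomical definition of
#' SRF as fluid between the neurosensory retina and the RPE.
#'
#' @param image intensity matrix in \[0, 1\].
#' @param strat_mask stratification mask aligned with `image` (gold or
#'   inferred).
#' @param config an [inference_config()].
#' @return Integer lesion mask (0 background, 1 SRF, 2 IRC).
#' @export
segment_fluid <- function(image, strat_mask, config = inference_config()) {
  if (!all(dim(image) == dim(strat_mask)))
    stopf("image and strat_mask dimensions differ")
  H <- nrow(image); W <- ncol(image)
  sm <- box_blur(image, 3L, 3L)
  cand <- sm < config$fluid_threshold & strat_mask == 1L
  lesion <- matrix(0L, H, W)
  if (!any(cand)) return(lesion)
  labels <- EBImage::bwlabel(matrix(as.numeric(cand), H, W))
  labels <- matrix(as.integer(labels), H, W)
  sizes <- tabulate(labels)
  rpe_row <- apply(strat_mask == 2L, 2L, function(v) {
    w <- which(v); if (length(w)) w[1L] else NA_integer_
  })
  for (k in which(sizes >= config$min_component_px)) {
    idx <- which(labels == k)
    rr <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    touches_rpe <- any(!is.na(rpe_row[cc]) & rr == rpe_row[cc] - 1L)
    lesion[idx] <- if (touches_rpe) 1L else 2L
  }
  lesion
}

#' Run the full inference backend on one scene image
#'
#' Convenience wrapper: traces the stratification mask, detects the fovea,
#' and segments fluid, returning a `retinal_scene` whose truth slot holds the
#' inferred measurements.
#'
#' @param image intensity matrix in \[0, 1\].
#' @param config an [inference_config()].
#' @param search_band passed to [detect_fovea()].
#' @return A `retinal_scene` built from the inferred masks.
#' @export
infer_scene <- function(image, config = inference_config(),
                        search_band = c(1 / 3, 2 / 3)) {
  strat <- trace_layer_boundaries(image, config)
  fovea <- detect_fovea(strat, search_band)
  lesion <- segment_fluid(image, strat, config)
  new_retinal_scene(image, strat, lesion,
                    if (is.na(fovea)) 0.5 else fovea)
}
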