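#' Simulated anti-VEGF treatment effect
#'
#' Multiplicative scalings applied to a pre-therapeutic scene to obtain the
#' "real" post-therapeutic anatomy: retinal thickening in excess of a healthy
#' baseline, cyst semi-axes, and SRF pocket heights each get their own factor.
#' A factor of 1 leaves the corresponding structure unchanged (up to
#' rasterization); a factor of 0 removes the fluid entirely, which is the
#' typical response to successful therapy.
#'
#' @param thickness_scale factor > 0 on thickening above the baseline.
#' @param cyst_scale factor >= 0 on cyst semi-axes.
#' @param srf_scale factor >= 0 on SRF pocket heights.
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(thickness_scale = 1, cyst_scale = 1,
                             srf_scale = 1) {
  if (thickness_scale <= 0) stopf("thickness_scale must be > 0")
  if (cyst_scale < 0 || srf_scale < 0)
    stopf("cyst_scale and srf_scale must be >= 0")
  structure(list(thickness_scale = thickness_scale,
                 cyst_scale = cyst_scale, srf_scale = srf_scale),
            class = "treatment_effect")
}

#' Apply a treatment effect to scene parameters
#'
#' Produces post-therapeutic [scene_params()]. Thickness scaling moves the ILM
#' curve toward the RPE so that thickening above `baseline_thickness` is
#' multiplied by `thickness_scale` (columns already at or below baseline are
#' untouched: therapy resolves edema, it does not thin a healthy retina).
#' Cysts keep their relative axial position within the class-1 band and their
#' semi-axes are scaled; SRF pocket heights are scaled. Because every change is
#' an analytic transformation of the parameters, the direction of every
#' ground-truth anatomical change is known exactly.
#'
#' @param params pre-therapeutic [scene_params()].
#' @param effect a [treatment_effect()].
#' @return Post-therapeutic `scene_params`.
#' @export
apply_treatment <- function(params, effect) {
  stopifnot(inherits(params, "scene_params"),
            inherits(effect, "treatment_effect"))
  p <- params
  base <- p$baseline_thickness
  thick <- p$rpe_curve - p$ilm_curve
  new_thick <- ifelse(thick > base,
                      base + effect$thickness_scale * (thick - base),
                      thick)
  new_ilm <- pmax(0, p$rpe_curve - new_thick)

  cysts <- p$cysts
  if (nrow(cysts) > 0L) {
    for (i in seq_len(nrow(cysts))) {
      j <- min(max(1L, round_half_away(cysts$cx[i]) + 1L), p$width)
      frac <- (cysts$cy[i] - p$ilm_curve[j]) / max(thick[j], 1e-9)
      cysts$cy[i] <- new_ilm[j] + frac * (p$rpe_curve[j] - new_ilm[j])
      cysts$ax[i] <- cysts$ax[i] * effect$cyst_scale
      cysts$ay[i] <- cysts$ay[i] * effect$cyst_scale
    }
    cysts <- cysts[cysts$ax > 0 & cysts$ay > 0, , drop = FALSE]
  }
  pockets <- p$srf_pockets
  if (nrow(pockets) > 0L) {
    pockets$max_height <- pockets$max_height * effect$srf_scale
    pockets <- pockets[pockets$max_height > 0, , drop = FALSE]
  }

  p$ilm_curve <- new_ilm
  p$cysts <- cysts
  p$srf_pockets <- pockets
  validate_scene_params(p, check_lesions = FALSE)
  p
}

#' Imperfection model for a predicted post-therapeutic scan
#'
#' Describes how a predicted (image-translated) B-scan deviates from the real
#' follow-up scan: laterally smoothed random displacement of the three layer
#' boundaries, morphological dilation/erosion of lesions, jitter of the
#' recorded fovea position, and — on demand — an injected structural
#' discontinuity of the kind that disqualifies predicted images (a contiguous
#' column range with the neuroepithelium band, the RPE/choroid band, or the
#' entire retina zeroed out).
#'
#' @param boundary_sd marginal sd (pixels) of the boundary displacement.
#' @param boundary_smooth lateral correlation window (columns, odd) of the
#'   displacement field.
#' @param lesion_dilate_px disc radius for lesion dilation (> 0) or erosion
#'   (< 0); 0 leaves lesions untouched.
#' @param fovea_sd sd of the jitter on the normalized fovea abscissa.
#' @param discontinuity `NULL`, or `list(type, columns)` with `type` one of
#'   `"neuroepithelium"`, `"rpe"`, `"entire"` and `columns` a 0-based
#'   inclusive column range `c(lo, hi)`.
#' @return An object of class `prediction_noise`.
#' @export
prediction_noise <- function(boundary_sd = 0, boundary_smooth = 15L,
                             lesion_dilate_px = 0L, fovea_sd = 0,
                             discontinuity = NULL) {
  if (boundary_sd < 0 || fovea_sd < 0) stopf("noise magnitudes must be >= 0")
  if (boundary_smooth < 1L) stopf("boundary_smooth must be >= 1")
  if (!is.null(discontinuity)) {
    if (!is.list(discontinuity) ||
          !all(c("type", "columns") %in% names(discontinuity)))
      stopf("discontinuity must be list(type, columns)")
    discontinuity$type <- match.arg(discontinuity$type,
                                    c("neuroepithelium", "rpe", "entire"))
    if (length(discontinuity$columns) != 2L)
      stopf("discontinuity$columns must be c(lo, hi)")
  }
  structure(list(boundary_sd = boundary_sd,
                 boundary_smooth = as.integer(boundary_smooth),
                 lesion_dilate_px = as.integer(lesion_dilate_px),
                 fovea_sd = fovea_sd,
                 discontinuity = discontinuity),
            class = "prediction_noise")
}

# Per-column boundary rows recovered from a stratification mask; NA where the
# column has no pixels of the class.
mask_boundaries <- function(strat) {
  first_row0 <- function(lgl_mat) {
    apply(lgl_mat, 2L, function(v) {
      w <- which(v)
      if (length(w)) w[1L] - 1L else NA_integer_
    })
  }
  last_row0 <- function(lgl_mat) {
    apply(lgl_mat, 2L, function(v) {
      w <- which(v)
      if (length(w)) w[length(w)] - 1L else NA_integer_
    })
  }
  list(ilm = first_row0(strat == 1L),
       rpe = first_row0(strat == 2L),
       choroid = last_row0(strat == 2L) + 1L)
}

morph_lesion <- function(bin, px) {
  if (px == 0L) return(bin)
  kern <- EBImage::makeBrush(2L * abs(px) + 1L, shape = "disc")
  out <- if (px > 0L) EBImage::dilate(bin, kern) else EBImage::erode(bin, kern)
  matrix(as.numeric(out) > 0, nrow(bin), ncol(bin))
}

#' Degrade a scene into a predicted-scan stand-in
#'
#' Returns an imperfect copy of a real post-therapeutic scene, standing in for
#' the output of an image-to-image translation model: layer boundaries are
#' displaced by a smoothed random field, lesions are dilated or eroded, the
#' fovea annotation is jittered, and an optional structural discontinuity is
#' carved out. The image is re-rendered from the degraded masks and `truth` is
#' recomputed from them, so the degraded scene remains internally consistent.
#' With all noise magnitudes zero and no discontinuity the input is returned
#' unchanged.
#'
#' @param scene a [generate_scene()] result.
#' @param noise a [prediction_noise()].
#' @param seed integer seed; the perturbation is a pure function of
#'   `(scene, noise, seed)`.
#' @return A degraded `retinal_scene`.
#' @export
perturb_prediction <- function(scene, noise = prediction_noise(), seed = 1L) {
  stopifnot(inherits(scene, "retinal_scene"),
            inherits(noise, "prediction_noise"))
  identity_noise <- noise$boundary_sd == 0 && noise$lesion_dilate_px == 0L &&
    noise$fovea_sd == 0 && is.null(noise$discontinuity)
  if (identity_noise) return(scene)

  height <- nrow(scene$strat_mask); width <- ncol(scene$strat_mask)
  withr::with_seed(seed, {
    strat <- scene$strat_mask
    lesion <- scene$lesion_mask
    fovea_x <- scene$fovea_x

    if (noise$boundary_sd > 0) {
      b <- mask_boundaries(strat)
      off <- function() round_half_away(
        smooth_noise(width, noise$boundary_sd, noise$boundary_smooth))
      ilm <- b$ilm + off(); rpe <- b$rpe + off(); cho <- b$choroid + off()
      ok <- !is.na(ilm) & !is.na(rpe) & !is.na(cho)
      # enforce ordering and image bounds per column
      ilm <- pmin(pmax(ilm, 0L), height - 3L)
      rpe <- pmin(pmax(rpe, ilm + 1L), height - 2L)
      cho <- pmin(pmax(cho, rpe), height - 1L)
      ilm[!ok] <- 0L; rpe[!ok] <- 0L; cho[!ok] <- 0L  # empty columns stay empty
      strat <- rasterize_strat(ilm, rpe, cho, width, height)
    }

    if (noise$lesion_dilate_px != 0L) {
      srf <- morph_lesion(lesion == 1L, noise$lesion_dilate_px)
      irc <- morph_lesion(lesion == 2L, noise$lesion_dilate_px)
      lesion <- matrix(0L, height, width)
      lesion[irc] <- 2L
      lesion[srf] <- 1L
    }
    lesion[strat != 1L] <- 0L

    if (!is.null(noise$discontinuity)) {
      cols <- noise$discontinuity$columns
      sel <- span_cols(cols[1L], cols[2L], width)
      if (length(sel)) {
        type <- noise$discontinuity$type
        sub <- strat[, sel, drop = FALSE]
        if (type %in% c("neuroepithelium", "entire")) sub[sub == 1L] <- 0L
        if (type %in% c("rpe", "entire")) sub[sub == 2L] <- 0L
        strat[, sel] <- sub
        lesion[, sel][strat[, sel] != 1L] <- 0L
      }
    }

    if (noise$fovea_sd > 0)
      fovea_x <- min(1, max(0, fovea_x + stats::rnorm(1, 0, noise$fovea_sd)))

    speckle <- if (!is.null(scene$params)) scene$params$speckle_level else 0
    refl <- if (!is.null(scene$params)) scene$params$reflectivity
            else oct_reflectivity()
    image <- render_scene_image(strat, lesion, speckle, refl)
    out <- new_retinal_scene(image, strat, lesion, fovea_x)
    out$params <- scene$params
    out
  })
}
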