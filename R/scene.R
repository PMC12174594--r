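#' Class reflectivities used to render phantom B-scans
#'
#' Mean reflectivity of each tissue class in the rendered intensity image,
#' on a \[0, 1\] scale. Fluid is hypo-reflective relative to the neurosensory
#' retina, and the sub-RPE (RPE-to-choroid) band is intermediate, which is what
#' makes the classical inference backend non-trivial but solvable.
#'
#' @param background reflectivity of the vitreous / sub-choroidal background.
#' @param retina reflectivity of the ILM-to-RPE band (class 1).
#' @param class2 reflectivity of the RPE-to-choroid band (class 2).
#' @param fluid reflectivity of SRF and IRC pixels.
#' @return A named list of four reflectivities.
#' @export
oct_reflectivity <- function(background = 0.05, retina = 0.55,
                             class2 = 0.35, fluid = 0.12) {
  vals <- c(background = background, retina = retina,
            class2 = class2, fluid = fluid)
  if (any(vals < 0 | vals > 1)) stopf("reflectivities must lie in [0, 1]")
  as.list(vals)
}

#' Parameters of one synthetic retinal B-scan
#'
#' Describes a layered retina by three per-column boundary curves (row of the
#' ILM upper limit, of the RPE upper limit, and of the choroid lower limit; row
#' 0 is the vitreous side at the top), a Gaussian foveal pit carved into the
#' ILM curve, elliptical intraretinal cysts, and parabolic subretinal fluid
#' pockets resting on the RPE. All coordinates are 0-based pixels; `fovea_x`
#' is normalized to image width.
#'
#' @param width,height image size in pixels (columns, rows).
#' @param ilm,rpe,choroid boundary rows, each a scalar or a length-`width`
#'   vector. `ilm` is the row of the inner retinal surface before the pit is
#'   applied; class 1 spans rows `[ilm, rpe)`, class 2 spans `[rpe, choroid)`.
#' @param fovea_x normalized foveal abscissa in \[0, 1\].
#' @param fovea_depth pit depth in pixels (the ILM dips this far toward the
#'   RPE at the fovea).
#' @param fovea_sigma lateral pit width (Gaussian sigma, pixels).
#' @param cysts `NULL` or a data frame with columns `cx, cy, ax, ay`: ellipse
#'   centers and semi-axes in pixels. Cysts must lie strictly inside the
#'   class-1 band.
#' @param srf_pockets `NULL` or a data frame with columns
#'   `x_start, x_end, max_height`: fluid pockets between the neuroepithelium
#'   and the RPE upper limit, with a parabolic height profile.
#' @param speckle_level standard deviation of the unit-mean multiplicative
#'   speckle applied to the rendered image (0 disables speckle).
#' @param baseline_thickness healthy retinal thickness in pixels; treatment
#'   scaling acts only on thickening in excess of this baseline (see
#'   [apply_treatment()]).
#' @param reflectivity see [oct_reflectivity()].
#' @param check_lesions validate that cysts and SRF pockets fit strictly
#'   inside the class-1 band (disabled internally when treatment scaling may
#'   legitimately shrink the band; rasterization always clips to the band).
#' @return An object of class `scene_params`.
#' @seealso [generate_scene()], [apply_treatment()]
#' @export
scene_params <- function(width = 256L, height = 192L,
                         ilm = 60, rpe = 120, choroid = 160,
                         fovea_x = 0.5, fovea_depth = 15,
                         fovea_sigma = width / 14,
                         cysts = NULL, srf_pockets = NULL,
                         speckle_level = 0.15,
                         baseline_thickness = 30,
                         reflectivity = oct_reflectivity(),
                         check_lesions = TRUE) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 8L || height < 8L) stopf("image must be at least 8 x 8 pixels")
  if (!is.numeric(fovea_x) || fovea_x < 0 || fovea_x > 1)
    stopf("fovea_x must lie in [0, 1], got %s", format(fovea_x))
  if (speckle_level < 0) stopf("speckle_level must be >= 0")
  if (baseline_thickness <= 0) stopf("baseline_thickness must be > 0")

  expand <- function(v, what) {
    if (length(v) == 1L) rep(as.numeric(v), width)
    else if (length(v) == width) as.numeric(v)
    else stopf("%s must be a scalar or length-%d vector", what, width)
  }
  ilm_curve <- expand(ilm, "ilm")
  rpe_curve <- expand(rpe, "rpe")
  choroid_curve <- expand(choroid, "choroid")

  # Foveal pit: Gaussian depression of the ILM toward the RPE.
  if (fovea_depth > 0) {
    x <- 0:(width - 1L)
    fx <- fovea_x * (width - 1L)
    ilm_curve <- ilm_curve +
      fovea_depth * exp(-0.5 * ((x - fx) / fovea_sigma)^2)
  }

  p <- structure(list(
    width = width, height = height,
    ilm_curve = ilm_curve, rpe_curve = rpe_curve,
    choroid_curve = choroid_curve,
    fovea_x = fovea_x,
    cysts = normalize_cysts(cysts),
    srf_pockets = normalize_pockets(srf_pockets, width),
    speckle_level = speckle_level,
    baseline_thickness = baseline_thickness,
    reflectivity = reflectivity
  ), class = "scene_params")
  validate_scene_params(p, check_lesions = check_lesions)
  p
}

normalize_cysts <- function(cysts) {
  if (is.null(cysts) || NROW(cysts) == 0L)
    return(data.frame(cx = numeric(), cy = numeric(),
                      ax = numeric(), ay = numeric()))
  cysts <- as.data.frame(cysts)
  need <- c("cx", "cy", "ax", "ay")
  if (!all(need %in% names(cysts)))
    stopf("cysts needs columns %s", paste(need, collapse = ", "))
  if (any(cysts$ax < 0 | cysts$ay < 0)) stopf("cyst semi-axes must be >= 0")
  cysts[need]
}

normalize_pockets <- function(pockets, width) {
  if (is.null(pockets) || NROW(pockets) == 0L)
    return(data.frame(x_start = numeric(), x_end = numeric(),
                      max_height = numeric()))
  pockets <- as.data.frame(pockets)
  need <- c("x_start", "x_end", "max_height")
  if (!all(need %in% names(pockets)))
    stopf("srf_pockets needs columns %s", paste(need, collapse = ", "))
  if (any(pockets$x_start > pockets$x_end))
    stopf("srf pocket has x_start > x_end")
  if (any(pockets$x_start < 0 | pockets$x_end > width - 1L))
    stopf("srf pocket outside image columns")
  if (any(pockets$max_height < 0)) stopf("srf pocket heights must be >= 0")
  pockets[need]
}

validate_scene_params <- function(p, check_lesions = TRUE) {
  bad <- which(!(p$ilm_curve < p$rpe_curve & p$rpe_curve <= p$choroid_curve &
                   p$ilm_curve >= 0 & p$choroid_curve < p$height))
  if (length(bad) > 0L)
    stopf("invalid layer ordering (need 0 <= ILM < RPE <= choroid < height) at column %d",
          bad[1L] - 1L)
  if (!check_lesions) return(invisible(p))
  if (nrow(p$cysts) > 0L) {
    for (i in seq_len(nrow(p$cysts))) {
      cy <- p$cysts[i, ]
      if (cy$ax == 0 || cy$ay == 0) next
      span <- span_cols(cy$cx - cy$ax, cy$cx + cy$ax, p$width)
      if (length(span) == 0L) next
      if (cy$cy - cy$ay <= max(p$ilm_curve[span]) ||
            cy$cy + cy$ay >= min(p$rpe_curve[span]))
        stopf("cyst %d is not strictly inside the class-1 band", i)
    }
  }
  if (nrow(p$srf_pockets) > 0L) {
    for (i in seq_len(nrow(p$srf_pockets))) {
      pk <- p$srf_pockets[i, ]
      span <- span_cols(pk$x_start, pk$x_end, p$width)
      if (pk$max_height >= min(p$rpe_curve[span] - p$ilm_curve[span]))
        stopf("srf pocket %d reaches above the neuroepithelium", i)
    }
  }
  invisible(p)
}

# 1-based column indices covered by a 0-based x interval, clipped to the image.
span_cols <- function(x0, x1, width) {
  lo <- max(0L, ceiling(x0)); hi <- min(width - 1L, floor(x1))
  if (lo > hi) integer() else (lo:hi) + 1L
}

# Integer boundary rows actually rasterized.
raster_curves <- function(p) {
  list(ilm = pmax(0L, round_half_away(p$ilm_curve)),
       rpe = round_half_away(p$rpe_curve),
       choroid = pmin(p$height, round_half_away(p$choroid_curve)))
}

rasterize_strat <- function(ilm, rpe, choroid, width, height) {
  rows <- matrix(0:(height - 1L), height, width)
  ilm_m <- matrix(ilm, height, width, byrow = TRUE)
  rpe_m <- matrix(rpe, height, width, byrow = TRUE)
  cho_m <- matrix(choroid, height, width, byrow = TRUE)
  m <- matrix(0L, height, width)
  m[rows >= ilm_m & rows < rpe_m] <- 1L
  m[rows >= rpe_m & rows < cho_m] <- 2L
  m
}

# SRF (label 1) sits on the RPE upper limit; cysts (label 2) are interior.
# Both are clipped to the class-1 band; SRF takes precedence on overlap.
rasterize_lesions <- function(p, strat, rc) {
  lesion <- matrix(0L, p$height, p$width)
  if (nrow(p$cysts) > 0L) {
    for (i in seq_len(nrow(p$cysts))) {
      cy <- p$cysts[i, ]
      if (cy$ax <= 0 || cy$ay <= 0) next
      cols <- span_cols(cy$cx - cy$ax, cy$cx + cy$ax, p$width)
      r0 <- max(0L, ceiling(cy$cy - cy$ay))
      r1 <- min(p$height - 1L, floor(cy$cy + cy$ay))
      if (r0 > r1 || length(cols) == 0L) next
      for (j in cols) {
        x <- j - 1L
        dy <- cy$ay * sqrt(max(0, 1 - ((x - cy$cx) / cy$ax)^2))
        rows <- seq.int(max(r0, ceiling(cy$cy - dy)),
                        min(r1, floor(cy$cy + dy)))
        rows <- rows[rows >= 0L & rows < p$height]
        if (length(rows)) {
          sel <- rows + 1L
          sel <- sel[strat[cbind(sel, j)] == 1L]
          lesion[cbind(sel, rep(j, length(sel)))] <- 2L
        }
      }
    }
  }
  if (nrow(p$srf_pockets) > 0L) {
    for (i in seq_len(nrow(p$srf_pockets))) {
      pk <- p$srf_pockets[i, ]
      cols <- span_cols(pk$x_start, pk$x_end, p$width)
      if (length(cols) == 0L || pk$max_height <= 0) next
      half <- max((pk$x_end - pk$x_start) / 2, 0.5)
      mid <- (pk$x_start + pk$x_end) / 2
      for (j in cols) {
        x <- j - 1L
        h <- round_half_away(pk$max_height * max(0, 1 - ((x - mid) / half)^2))
        if (h <= 0) next
        rows <- seq.int(rc$rpe[j] - h, rc$rpe[j] - 1L)
        rows <- rows[rows >= 0L & rows < p$height]
        sel <- rows + 1L
        sel <- sel[strat[cbind(sel, j)] == 1L]
        if (length(sel)) lesion[cbind(sel, rep(j, length(sel)))] <- 1L
      }
    }
  }
  lesion
}

render_scene_image <- function(strat, lesion, speckle_level, refl) {
  img <- matrix(refl$background, nrow(strat), ncol(strat))
  img[strat == 1L] <- refl$retina
  img[strat == 2L] <- refl$class2
  img[lesion > 0L] <- refl$fluid
  if (speckle_level > 0) {
    k <- 1 / speckle_level^2
    img <- img * matrix(stats::rgamma(length(img), shape = k, rate = k),
                        nrow(img), ncol(img))
  }
  pmin(pmax(img, 0), 1)
}

new_retinal_scene <- function(image, strat, lesion, fovea_x) {
  structure(list(
    image = image,
    strat_mask = strat,
    lesion_mask = lesion,
    fovea_x = fovea_x,
    truth = anatomy_measurements(strat, lesion, fovea_x)
  ), class = "retinal_scene")
}

#' Generate one synthetic retinal B-scan phantom
#'
#' Rasterizes the layer curves and lesions of a [scene_params()] description
#' into a stratification mask (class 0 background, class 1 ILM-to-RPE, class 2
#' RPE-to-choroid), a lesion mask (class 0 background, class 1 SRF, class 2
#' IRC), and a rendered intensity image with multiplicative speckle. The
#' scene's `truth` slot holds the anatomical measurements recomputed from the
#' masks, so ground truth is by construction consistent with the rasters.
#'
#' @param params a [scene_params()] object.
#' @param seed integer seed for the speckle noise; the same `(params, seed)`
#'   pair always yields a bit-identical scene.
#' @return An object of class `retinal_scene` with elements `image` (matrix in
#'   \[0, 1\]), `strat_mask`, `lesion_mask` (integer matrices), `fovea_x`, and
#'   `truth` (an `anatomy_measurements` list).
#' @examples
#' sc <- generate_scene(scene_params(width = 96, height = 96, ilm = 20,
#'                                   rpe = 50, choroid = 70, fovea_depth = 8),
#'                      seed = 1)
#' sc$truth$crt
#' @export
generate_scene <- function(params, seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  validate_scene_params(params, check_lesions = FALSE)
  rc <- raster_curves(params)
  strat <- rasterize_strat(rc$ilm, rc$rpe, rc$choroid,
                           params$width, params$height)
  lesion <- rasterize_lesions(params, strat, rc)
  image <- withr::with_seed(seed,
    render_scene_image(strat, lesion, params$speckle_level,
                       params$reflectivity))
  sc <- new_retinal_scene(image, strat, lesion, params$fovea_x)
  sc$params <- params
  sc$seed <- as.integer(seed)
  sc
}

#' @export
print.retinal_scene <- function(x, ...) {
  cat(sprintf("<retinal_scene> %d x %d px, fovea_x = %.3f\n",
              ncol(x$image), nrow(x$image), x$fovea_x))
  cat(sprintf("  CRT %.1f, max thickness %.1f, SRF %d px, IRC %d px\n",
              x$truth$crt, x$truth$max_thickness,
              x$truth$srf_area, x$truth$irc_area))
  invisible(x)
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("<scene_params> %d x %d px, %d cyst(s), %d SRF pocket(s), speckle %.2f\n",
              x$width, x$height, nrow(x$cysts), nrow(x$srf_pockets),
              x$speckle_level))
  invisible(x)
}
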