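#' Specification of a synthetic paired pre/post cohort
#'
#' Defines the distributions from which paired pre-therapeutic scenes,
#' real post-therapeutic scenes (known treatment effect), and imperfect
#' predicted post-therapeutic scenes are drawn. Identical specifications
#' (including `seed`) always produce bit-identical cohorts.
#'
#' The default ranges describe an edematous macula: a retina thickened well
#' beyond the 30-px healthy baseline, a central foveal pit, up to three
#' intraretinal cysts, subretinal fluid in roughly half of eyes, and a
#' treatment that usually — but not always — reduces thickening and fluid,
#' mirroring the predominance of decreases over increases in anti-VEGF
#' follow-up.
#'
#' @param n_pairs number of pre/post pairs (>= 1).
#' @param width,height scene size in pixels.
#' @param param_ranges named list of sampling ranges for the pre-therapeutic
#'   [scene_params()] fields; see Details. Partial lists override defaults.
#' @param effect_ranges named list with entries `thickness_scale`,
#'   `cyst_scale`, `srf_scale`, each a `c(min, max)` range for the uniform
#'   draw of the [treatment_effect()].
#' @param predicted_noise a [prediction_noise()] describing the predicted-scan
#'   degradation, plus optional element-wise override via
#'   `p_discontinuity` (probability of injecting a random discontinuity).
#' @param p_discontinuity probability that a predicted scan receives an
#'   injected structural discontinuity.
#' @param seed integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 37L, width = 256L, height = 192L,
                        param_ranges = list(),
                        effect_ranges = list(),
                        predicted_noise = prediction_noise(
                          boundary_sd = 1.5, boundary_smooth = 15L,
                          lesion_dilate_px = -1L, fovea_sd = 0.01),
                        p_discontinuity = 0,
                        seed = 1L) {
  if (n_pairs < 1L) stopf("n_pairs must be >= 1")
  # default ranges are expressed for a 256 x 192 scene and scaled to the
  # requested size; explicit overrides are taken as absolute pixels
  sy <- height / 192; sx <- width / 256
  pr <- utils::modifyList(list(
    ilm = sy * c(45, 65),
    thickness = sy * c(45, 90),   # pre-therapeutic band thickness (edema)
    class2_depth = sy * c(28, 42),
    fovea_x = c(0.38, 0.62),
    fovea_depth = sy * c(6, 16),
    n_cysts = c(0L, 3L),
    cyst_ax = sx * c(5, 14),
    cyst_ay = sy * c(3, 8),
    p_srf = 0.5,
    srf_halfwidth = sx * c(15, 45),
    srf_height = sy * c(5, 14),
    speckle = 0.15
  ), param_ranges)
  er <- utils::modifyList(list(
    thickness_scale = c(0.3, 1.3),
    cyst_scale = c(0, 1.2),
    srf_scale = c(0, 1.2)
  ), effect_ranges)
  for (nm in names(pr)) {
    v <- pr[[nm]]
    if (length(v) == 2L && is.numeric(v) && v[1L] > v[2L])
      stopf("param_ranges$%s has min > max", nm)
  }
  for (nm in names(er)) {
    v <- er[[nm]]
    if (v[1L] > v[2L]) stopf("effect_ranges$%s has min > max", nm)
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 width = as.integer(width), height = as.integer(height),
                 param_ranges = pr, effect_ranges = er,
                 predicted_noise = predicted_noise,
                 p_discontinuity = p_discontinuity,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

runifr <- function(r) stats::runif(1L, r[1L], r[2L])

sample_scene_params <- function(spec) {
  pr <- spec$param_ranges
  W <- spec$width; H <- spec$height
  ilm0 <- runifr(pr$ilm)
  thick <- runifr(pr$thickness)
  rpe0 <- ilm0 + thick
  cho0 <- min(rpe0 + runifr(pr$class2_depth), H - 2L)
  fovea_x <- runifr(pr$fovea_x)
  fovea_depth <- min(runifr(pr$fovea_depth), thick - 8)

  p <- scene_params(width = W, height = H, ilm = ilm0, rpe = rpe0,
                    choroid = cho0, fovea_x = fovea_x,
                    fovea_depth = max(fovea_depth, 0),
                    speckle_level = pr$speckle, check_lesions = FALSE)

  # cysts: sampled strictly inside the (pit-deformed) class-1 band
  n_cysts <- sample(pr$n_cysts[1L]:pr$n_cysts[2L], 1L)
  cysts <- NULL
  if (n_cysts > 0L) {
    rows <- vector("list", n_cysts)
    for (i in seq_len(n_cysts)) {
      cx <- stats::runif(1L, 0.15 * W, 0.85 * W)
      ax <- runifr(pr$cyst_ax)
      span <- span_cols(cx - ax, cx + ax, W)
      top <- max(p$ilm_curve[span]); bot <- min(p$rpe_curve[span])
      ay_max <- (bot - top - 4) / 2
      if (ay_max < 2) next
      ay <- min(runifr(pr$cyst_ay), ay_max)
      cy <- stats::runif(1L, top + ay + 1.5, bot - ay - 1.5)
      rows[[i]] <- data.frame(cx = cx, cy = cy, ax = ax, ay = ay)
    }
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (length(rows)) cysts <- do.call(rbind, rows)
  }

  pockets <- NULL
  if (stats::runif(1L) < pr$p_srf) {
    xc <- stats::runif(1L, 0.25 * W, 0.75 * W)
    hw <- runifr(pr$srf_halfwidth)
    xs <- max(0, xc - hw); xe <- min(W - 1L, xc + hw)
    span <- span_cols(xs, xe, W)
    h_max <- min(p$rpe_curve[span] - p$ilm_curve[span]) - 6
    h <- min(runifr(pr$srf_height), h_max)
    if (h >= 2)
      pockets <- data.frame(x_start = xs, x_end = xe, max_height = h)
  }

  p$cysts <- normalize_cysts(cysts)
  p$srf_pockets <- normalize_pockets(pockets, W)
  validate_scene_params(p, check_lesions = TRUE)
  p
}

sample_effect <- function(spec) {
  er <- spec$effect_ranges
  treatment_effect(thickness_scale = max(runifr(er$thickness_scale), 0.05),
                   cyst_scale = runifr(er$cyst_scale),
                   srf_scale = runifr(er$srf_scale))
}

#' Generate a paired pre/post/predicted phantom cohort
#'
#' For each pair: a pre-therapeutic scene is sampled, a treatment effect is
#' drawn and applied to obtain the real post-therapeutic scene, and the
#' predicted post-therapeutic scene is produced by degrading the real one with
#' the spec's [prediction_noise()]. With zero prediction noise the predicted
#' scan equals the real follow-up, so downstream trend prediction is perfect
#' by construction.
#'
#' Ground-truth trend labels (real post vs pre, classified with `rule` on the
#' scenes' `truth` values) are recorded in the cohort's `truth` data frame for
#' all four anatomical quantities.
#'
#' @param spec a [cohort_spec()].
#' @param rule the [trend_rule()] used for the recorded ground-truth labels.
#' @return An object of class `oct_cohort`: `pairs`, a list of
#'   `list(pre, post_real, post_predicted)` scenes, plus `truth`, a data frame
#'   of per-pair ground-truth measurements and trend labels, and `spec`.
#' @export
generate_cohort <- function(spec, rule = trend_rule()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    pairs <- vector("list", spec$n_pairs)
    rows <- vector("list", spec$n_pairs)
    for (i in seq_len(spec$n_pairs)) {
      params_pre <- sample_scene_params(spec)
      effect <- sample_effect(spec)
      params_post <- apply_treatment(params_pre, effect)
      seeds <- sample.int(.Machine$integer.max, 3L)
      pre <- generate_scene(params_pre, seed = seeds[1L])
      post_real <- generate_scene(params_post, seed = seeds[2L])
      noise <- spec$predicted_noise
      if (spec$p_discontinuity > 0 &&
            stats::runif(1L) < spec$p_discontinuity) {
        lo <- sample.int(spec$width - 30L, 1L) - 1L
        noise$discontinuity <- list(
          type = sample(c("neuroepithelium", "rpe", "entire"), 1L),
          columns = c(lo, lo + sample(8:25, 1L)))
      }
      post_pred <- perturb_prediction(post_real, noise, seed = seeds[3L])
      pairs[[i]] <- list(pre = pre, post_real = post_real,
                         post_predicted = post_pred)
      lab <- function(q, fluid) classify_trend(pre$truth[[q]],
                                               post_real$truth[[q]],
                                               rule, is_fluid = fluid)$value
      rows[[i]] <- data.frame(
        pair_id = i,
        crt_pre = pre$truth$crt, crt_post = post_real$truth$crt,
        max_thickness_pre = pre$truth$max_thickness,
        max_thickness_post = post_real$truth$max_thickness,
        srf_area_pre = pre$truth$srf_area,
        srf_area_post = post_real$truth$srf_area,
        irc_area_pre = pre$truth$irc_area,
        irc_area_post = post_real$truth$irc_area,
        trend_crt = lab("crt", FALSE),
        trend_max_thickness = lab("max_thickness", FALSE),
        trend_srf_area = lab("srf_area", TRUE),
        trend_irc_area = lab("irc_area", TRUE)
      )
    }
    structure(list(pairs = pairs, truth = do.call(rbind, rows), spec = spec),
              class = "oct_cohort")
  })
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf("<oct_cohort> %d pairs, %d x %d px, seed %d\n",
              length(x$pairs), x$spec$width, x$spec$height, x$spec$seed))
  print(table(CRT_trend = x$truth$trend_crt))
  invisible(x)
}
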