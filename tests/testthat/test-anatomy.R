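test_that("thickness profile counts class-1 pixels per column", {
  m <- matrix(0L, 60, 20)
  m[11:50, ] <- 1L
  expect_equal(unname(thickness_profile(m)), rep(40, 20))
  expect_equal(unname(thickness_profile(m, pixel_geometry(axial_um_per_px = 3))),
               rep(120, 20))
  expect_warning(p0 <- thickness_profile(matrix(0L, 4, 4)), "no retina")
  expect_equal(unname(p0), rep(0, 4))
  expect_error(thickness_profile(matrix(5L, 2, 2)), "labels")
})

test_that("CRT reads the profile at the rounded fovea column", {
  m <- matrix(0L, 60, 21)
  m[11:50, ] <- 1L
  m[11:20, 11] <- 0L  # 30-px column at the center (0-based column 10)
  expect_equal(central_retinal_thickness(m, 0.5), 30)
  expect_equal(central_retinal_thickness(m, 0), 40)
  expect_error(central_retinal_thickness(m, 1.3), "fovea_x")
})

test_that("fovea pit minimum sits at the pit column with the pit depth", {
  p <- scene_params(width = 160L, height = 128L, ilm = 40, rpe = 90,
                    choroid = 120, fovea_x = 0.5, fovea_depth = 15,
                    speckle_level = 0)
  sc <- generate_scene(p, seed = 1)
  prof <- thickness_profile(sc$strat_mask)
  expect_equal(which.min(prof), 80 + 1, tolerance = 1)  # fovea column 0.5*(W-1)
  expect_equal(min(prof), 50 - 15, tolerance = 1)
  expect_equal(sc$truth$crt, min(prof))
})

test_that("maximal thickness is the brute-force column maximum", {
  m <- matrix(0L, 80, 30)
  m[21:60, ] <- 1L           # 40 px
  m[9:60, 12:14] <- 1L       # a 12-px bulge
  expect_equal(maximal_retinal_thickness(m), 52)
  expect_warning(expect_equal(maximal_retinal_thickness(matrix(0L, 5, 5)), 0))
})

test_that("lesion areas are exhaustive pixel counts with opt-in unit conversion", {
  m <- matrix(0L, 5, 5)
  m[cbind(c(1, 2, 3), c(1, 1, 2))] <- 1L
  m[cbind(c(1, 1, 2, 3, 4, 5, 5), c(4, 5, 5, 4, 4, 4, 5))] <- 2L
  expect_equal(lesion_areas(m), c(srf_area = 3, irc_area = 7))
  g <- pixel_geometry(lateral_um_per_px = 2, axial_um_per_px = 3)
  expect_equal(lesion_areas(m, g), c(srf_area = 18, irc_area = 42))
  expect_equal(lesion_areas(matrix(0L, 4, 4)), c(srf_area = 0, irc_area = 0))
})

test_that("lesion areas match the brute-force oracle on random masks", {
  set.seed(31)
  for (i in 1:20) {
    m <- random_mask(sample(4:20, 1), sample(4:20, 1))
    expect_equal(unname(lesion_areas(m)),
                 unname(as.numeric(brute_lesion_counts(m))))
  }
})

test_that("crt never exceeds maximal thickness across a cohort", {
  coh <- generate_cohort(cohort_spec(n_pairs = 4L, width = 128L,
                                     height = 112L, seed = 17))
  for (pair in coh$pairs) {
    for (sc in pair) expect_lte(sc$truth$crt, sc$truth$max_thickness)
  }
})

test_that("trend labels are invariant under a common unit rescaling", {
  set.seed(5)
  pre <- runif(50, 10, 300); post <- runif(50, 10, 300)
  for (k in c(0.01, 8.789, 1000)) {
    for (i in seq_along(pre)) {
      expect_identical(classify_trend(pre[i], post[i])$value,
                       classify_trend(k * pre[i], k * post[i])$value)
    }
  }
})

test_that("fovea displacement and tolerance accuracy behave as specified", {
  expect_equal(fovea_displacement(0.5, 0.5), 0)
  expect_equal(fovea_displacement(0.52, 0.50), 0.02)
  expect_error(fovea_displacement(1.2, 0.5), "\\[0, 1\\]")
  # injected normal localization noise: accuracy approx 2*pnorm(tau/sd) - 1
  set.seed(8)
  gold <- runif(2000, 0.3, 0.7)
  pred <- pmin(1, pmax(0, gold + rnorm(2000, 0, 0.01)))
  acc <- fovea_accuracy(pred, gold, tol = 0.02)
  expect_equal(acc$accuracy, 2 * pnorm(2) - 1, tolerance = 0.02)
  expect_equal(acc$mean, 0.01 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("continuity flags detect constructed gaps and ignore sub-threshold ones", {
  p <- demo_params(speckle = 0)
  sc <- generate_scene(p, seed = 1)
  expect_false(any(unlist(continuity_flags(sc$strat_mask)[1:3])))

  for (type in c("neuroepithelium", "rpe", "entire")) {
    out <- perturb_prediction(
      sc, prediction_noise(discontinuity = list(type = type,
                                                columns = c(40, 52))),
      seed = 1)
    fl <- continuity_flags(out$strat_mask, min_gap_columns = 3L)
    expect_true(fl[[paste0(type, "_discontinuity")]])
    if (type == "entire") {
      expect_true(fl$neuroepithelium_discontinuity)
      expect_true(fl$rpe_discontinuity)
    }
  }

  # single-column dropout stays below the min_gap threshold
  m <- sc$strat_mask
  m[, 70] <- 0L
  fl <- continuity_flags(m, min_gap_columns = 3L)
  expect_false(fl$neuroepithelium_discontinuity)
  expect_false(fl$rpe_discontinuity)
  expect_false(fl$entire_discontinuity)
})
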