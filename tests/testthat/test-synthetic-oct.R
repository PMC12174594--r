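test_that("flat-layer scene has the geometry forced by its curves", {
  p <- scene_params(width = 160L, height = 128L, ilm = 40, rpe = 80,
                    choroid = 120, fovea_depth = 0, speckle_level = 0)
  sc <- generate_scene(p, seed = 1)
  expect_equal(unname(thickness_profile(sc$strat_mask)), rep(40, 160))
  expect_equal(sc$truth$srf_area, 0)
  expect_equal(sc$truth$irc_area, 0)
  expect_equal(sc$truth$crt, 40)
  expect_equal(sc$truth$max_thickness, 40)
  # class bands rendered at distinct mean reflectivities, fluid-free
  expect_setequal(unique(as.vector(sc$strat_mask)), c(0L, 1L, 2L))
})

test_that("rasterized cyst area equals the brute-force ellipse pixel count", {
  p <- scene_params(width = 160L, height = 128L, ilm = 30, rpe = 90,
                    choroid = 118, fovea_depth = 0,
                    cysts = data.frame(cx = 70.3, cy = 61.2, ax = 6, ay = 4),
                    speckle_level = 0)
  sc <- generate_scene(p, seed = 1)
  expect_equal(sc$truth$irc_area,
               brute_ellipse_area(70.3, 61.2, 6, 4, 160L, 128L))
  expect_true(all(sc$strat_mask[sc$lesion_mask == 2L] == 1L))
})

test_that("generation is a pure function of (params, seed)", {
  p <- demo_params()
  a <- generate_scene(p, seed = 42)
  b <- generate_scene(p, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$strat_mask, b$strat_mask)
  expect_identical(a$lesion_mask, b$lesion_mask)
  c <- generate_scene(p, seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("invalid layer ordering is rejected naming the offending column", {
  rpe <- rep(80, 160); rpe[31] <- 30  # RPE above ILM at column 30 (0-based)
  expect_error(
    scene_params(width = 160L, height = 128L, ilm = 40, rpe = rpe,
                 choroid = 120, fovea_depth = 0),
    "column 30")
})

test_that("scene truth equals brute-force measurement from the masks", {
  set.seed(11)
  for (rep in 1:5) {
    spec <- cohort_spec(n_pairs = 1L, width = 128L, height = 112L,
                        seed = 100 + rep)
    sc <- generate_cohort(spec)$pairs[[1]]$pre
    bf <- brute_truth(sc)
    expect_equal(sc$truth$crt, bf$crt)
    expect_equal(sc$truth$max_thickness, bf$max_thickness)
    expect_equal(sc$truth$srf_area, bf$srf_area)
    expect_equal(sc$truth$irc_area, bf$irc_area)
    # SRF pixels live inside the class-1 band by the rasterizer's convention
    expect_true(all(sc$strat_mask[sc$lesion_mask == 1L] == 1L))
  }
})

test_that("removing all fluid yields the both-zero no-change condition", {
  p <- demo_params(speckle = 0)
  post <- apply_treatment(p, treatment_effect(cyst_scale = 0, srf_scale = 0))
  sc <- generate_scene(post, seed = 1)
  expect_equal(sc$truth$irc_area, 0)
  expect_equal(sc$truth$srf_area, 0)
  lab <- classify_trend(0, 0, is_fluid = TRUE)
  expect_equal(lab$value, "no_change")
  expect_false(lab$adjudication_needed)
})

test_that("identity treatment reproduces the pre-therapeutic truth", {
  p <- demo_params(speckle = 0)
  post <- apply_treatment(p, treatment_effect(1, 1, 1))
  pre_sc <- generate_scene(p, seed = 5)
  post_sc <- generate_scene(post, seed = 5)
  expect_equal(post_sc$truth$crt, pre_sc$truth$crt, tolerance = 1e-12)
  expect_identical(post_sc$strat_mask, pre_sc$strat_mask)
  expect_identical(post_sc$lesion_mask, pre_sc$lesion_mask)
})

test_that("thickness scaling acts on thickening above the baseline", {
  # 40 px of thickening above a 20 px baseline, halved -> 20 px above baseline
  p <- scene_params(width = 120L, height = 128L, ilm = 40, rpe = 100,
                    choroid = 124, fovea_depth = 0, speckle_level = 0,
                    baseline_thickness = 20)
  post <- apply_treatment(p, treatment_effect(thickness_scale = 0.5))
  expect_equal(unique(post$rpe_curve - post$ilm_curve), 40)
  sc <- generate_scene(post, seed = 1)
  expect_equal(sc$truth$max_thickness, 40)
})

test_that("true anatomy responds monotonically to the effect scales", {
  p <- demo_params(speckle = 0)
  irc <- vapply(c(0, 0.4, 0.8, 1.2), function(s) {
    generate_scene(apply_treatment(p, treatment_effect(cyst_scale = s)),
                   seed = 1)$truth$irc_area
  }, numeric(1))
  expect_true(all(diff(irc) >= 0))
  srf <- vapply(c(0, 0.5, 1, 1.3), function(s) {
    generate_scene(apply_treatment(p, treatment_effect(srf_scale = s)),
                   seed = 1)$truth$srf_area
  }, numeric(1))
  expect_true(all(diff(srf) >= 0))
  crt <- vapply(c(0.3, 0.7, 1, 1.3), function(s) {
    generate_scene(apply_treatment(p, treatment_effect(thickness_scale = s)),
                   seed = 1)$truth$crt
  }, numeric(1))
  expect_true(all(diff(crt) >= 0))
})

test_that("zero prediction noise returns the scene unchanged", {
  sc <- generate_scene(demo_params(), seed = 3)
  out <- perturb_prediction(sc, prediction_noise(), seed = 9)
  expect_identical(out$strat_mask, sc$strat_mask)
  expect_identical(out$lesion_mask, sc$lesion_mask)
  expect_identical(out$image, sc$image)
})

test_that("an injected entire-retina defect is visible in the masks and flagged", {
  sc <- generate_scene(demo_params(speckle = 0), seed = 3)
  noise <- prediction_noise(
    discontinuity = list(type = "entire", columns = c(50, 60)))
  out <- perturb_prediction(sc, noise, seed = 1)
  cols <- 51:61  # 1-based
  expect_true(all(out$strat_mask[, cols] == 0L))
  fl <- continuity_flags(out$strat_mask, min_gap_columns = 3L)
  expect_true(fl$entire_discontinuity)
  gap <- fl$gap_columns[fl$gap_columns$type == "entire", ]
  expect_true(any(gap$start <= 50 & gap$end >= 60))
})

test_that("boundary jitter of sd 2 px yields mean absolute CRT error in [1, 4] px", {
  set.seed(21)
  noise <- prediction_noise(boundary_sd = 2, boundary_smooth = 15L)
  errs <- vapply(1:200, function(i) {
    sc <- generate_scene(demo_params(speckle = 0), seed = i)
    pert <- perturb_prediction(sc, noise, seed = 1000 + i)
    abs(pert$truth$crt - sc$truth$crt)
  }, numeric(1))
  expect_gte(mean(errs), 1)
  expect_lte(mean(errs), 4)
})

test_that("cohorts have the requested size, are deterministic, and validate ranges", {
  spec <- cohort_spec(n_pairs = 3L, width = 128L, height = 112L, seed = 5)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_length(coh1$pairs, 3L)
  expect_identical(coh1$truth, coh2$truth)
  expect_identical(coh1$pairs[[2]]$post_predicted$image,
                   coh2$pairs[[2]]$post_predicted$image)
  expect_named(coh1$pairs[[1]], c("pre", "post_real", "post_predicted"))
  expect_error(cohort_spec(param_ranges = list(thickness = c(90, 45))),
               "min > max")
  expect_error(cohort_spec(n_pairs = 0), "n_pairs")
})

test_that("scene and cohort round-trip through PNG/JSON/CSV files", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(demo_params(), seed = 2)
  write_scene(sc, dir, "scan01")
  back <- read_scene(dir, "scan01")
  expect_identical(back$strat_mask, sc$strat_mask)
  expect_identical(back$lesion_mask, sc$lesion_mask)
  expect_equal(back$fovea_x, sc$fovea_x)
  expect_equal(back$truth$irc_area, sc$truth$irc_area)
  expect_equal(max(abs(back$image - sc$image)), 0, tolerance = 1 / 254)

  spec <- cohort_spec(n_pairs = 2L, width = 96L, height = 96L,
                      param_ranges = list(ilm = c(20, 25),
                                          thickness = c(30, 40),
                                          class2_depth = c(15, 20),
                                          srf_height = c(4, 8)),
                      seed = 3)
  manifest <- write_cohort(generate_cohort(spec), dir)
  man <- read.csv(manifest)
  expect_equal(nrow(man), 2L)
  expect_true(all(c("trend_crt", "trend_srf_area") %in% names(man)))
  expect_true(file.exists(file.path(dir, "pair_002", "post_real_image.png")))
})
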