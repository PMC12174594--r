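test_that("the 10% relative-change rule classifies as written", {
  expect_equal(classify_trend(100, 115)$value, "increase")
  expect_equal(classify_trend(115, 100)$value, "decrease")
  lab <- classify_trend(100, 105)
  expect_equal(lab$value, "no_change")
  expect_true(lab$adjudication_needed)
  # asymmetric margins: decrease requires post < pre / 1.1, not post < 0.9 pre
  expect_equal(classify_trend(100, 91)$value, "no_change")
  expect_equal(classify_trend(100, 90.5)$value, "decrease")
  # fluid conventions
  expect_equal(classify_trend(0, 0, is_fluid = TRUE)$value, "no_change")
  expect_false(classify_trend(0, 0, is_fluid = TRUE)$adjudication_needed)
  expect_equal(classify_trend(0, 5, is_fluid = TRUE)$value, "increase")
  expect_error(classify_trend(-1, 5), "non-negative")
  expect_error(classify_trend(100, 105, trend_rule(tie_policy = "error")),
               "tie zone")
})

test_that("every non-negative pair maps to exactly one label, scale-invariantly", {
  set.seed(61)
  labels <- c("decrease", "no_change", "increase")
  for (i in 1:200) {
    pre <- runif(1, 0, 500); post <- runif(1, 0, 500)
    lab <- classify_trend(pre, post)
    expect_true(lab$value %in% labels)
    k <- runif(1, 0.001, 1000)
    expect_identical(classify_trend(k * pre, k * post)$value, lab$value)
  }
})

test_that("presence dichotomy uses a strict threshold", {
  expect_false(classify_presence(0))
  expect_true(classify_presence(1))
  expect_false(classify_presence(5, min_area = 5))
  expect_true(classify_presence(5.1, min_area = 5))
})

test_that("trend tables reproduce printed counts, margins, and accuracy", {
  tabs <- reported_trend_tables()
  crt <- tabs$crt_trend
  expect_equal(unname(crt["decrease", ]), c(23L, 4L))
  expect_equal(unname(crt["increase", ]), c(7L, 3L))
  m <- margin_totals(crt)
  expect_equal(unname(m$row_totals), c(27L, 10L))
  expect_equal(unname(m$col_totals), c(30L, 7L))
  expect_equal(m$total, 37L)
  expect_equal(table_accuracy(crt), 26 / 37)
  expect_equal(round(table_accuracy(crt), 2), 0.70)
  expect_equal(table_accuracy(tabs$srf_trend), 34 / 37)
  expect_equal(round(table_accuracy(tabs$srf_trend), 2), 0.92)

  built <- build_trend_table(
    c(rep("decrease", 27), rep("increase", 10)),
    c(rep("decrease", 23), rep("increase", 4),
      rep("decrease", 7), rep("increase", 3)),
    label_set = c("decrease", "increase"))
  expect_equal(unclass(built), unclass(crt))

  expect_error(build_trend_table(character(), character()), "empty")
  expect_error(build_trend_table("up", "down"), "unknown")
  diag_tab <- build_trend_table(rep("decrease", 5), rep("decrease", 5))
  expect_equal(table_accuracy(diag_tab), 1)
})

test_that("binary metrics reproduce the published presence evaluations", {
  tabs <- reported_trend_tables()
  srf <- binary_metrics(tabs$srf_presence, "present")
  expect_equal(srf$accuracy$value, 32 / 37)
  expect_equal(srf$sensitivity$value, 0)
  expect_equal(srf$specificity$value, 32 / 33)
  expect_equal(round(srf$sensitivity$ci[["high"]], 2), 0.60)

  irc <- binary_metrics(tabs$irc_presence, "present")
  expect_equal(irc$accuracy$value, 24 / 37)
  expect_equal(irc$sensitivity$value, 5 / 15)
  expect_equal(irc$specificity$value, 19 / 22)

  perfect <- build_trend_table(c(rep("absent", 3), rep("present", 3)),
                               c(rep("absent", 3), rep("present", 3)),
                               label_set = c("absent", "present"))
  pm <- binary_metrics(perfect, "present")
  expect_equal(pm$accuracy$value, 1)
  expect_equal(pm$sensitivity$value, 1)
  expect_equal(pm$specificity$value, 1)

  # a metric with no real cases of its class is marked undefined
  onesided <- build_trend_table(rep("absent", 4), rep("absent", 4),
                                label_set = c("absent", "present"))
  om <- binary_metrics(onesided, "present")
  expect_true(is.na(om$sensitivity$value))
  expect_null(om$sensitivity$ci)
})

test_that("Clopper-Pearson intervals match closed forms at the boundaries", {
  ci <- clopper_pearson(0, 4)
  expect_equal(ci[["low"]], 0)
  expect_equal(ci[["high"]], 1 - 0.025^(1 / 4))
  expect_equal(round(ci[["high"]], 2), 0.60)
  mirror <- clopper_pearson(4, 4)
  expect_equal(mirror[["low"]], 0.025^(1 / 4))
  expect_equal(mirror[["high"]], 1)
  expect_equal(clopper_pearson(0, 1)[["high"]], 0.975)
  expect_error(clopper_pearson(3, 0), "trials")
  expect_error(clopper_pearson(5, 4), "successes")
})

test_that("recomputed headline metrics agree with every printed value", {
  rep <- replicate_reported_metrics()
  get <- function(q, m) rep$value[rep$quantity == q & rep$metric == m]
  expect_equal(round(get("crt_trend", "accuracy"), 2), 0.70)
  expect_equal(round(get("max_thickness_trend", "accuracy"), 2), 0.70)
  expect_equal(round(get("srf_trend", "accuracy"), 2), 0.92)
  expect_equal(round(get("irc_trend", "accuracy"), 2), 0.78)
  expect_equal(round(get("srf_presence", "accuracy"), 2), 0.86)
  expect_equal(round(get("srf_presence", "specificity"), 2), 0.97)
  expect_equal(get("srf_presence", "sensitivity"), 0)
  expect_equal(round(get("irc_presence", "accuracy"), 2), 0.65)
  expect_equal(round(get("irc_presence", "specificity"), 2), 0.86)
  expect_equal(round(get("irc_presence", "sensitivity"), 2), 0.33)
})
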