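quantity_info <- function() {
  data.frame(
    quantity = c("crt", "max_thickness", "srf_area", "irc_area"),
    is_fluid = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' Measure every scan of a cohort
#'
#' Produces the per-scan measurement rows feeding [build_report()]. The
#' `"mask"` backend measures the scenes' own (gold) masks; the `"image"`
#' backend first runs the classical inference chain
#' ([trace_layer_boundaries()], [detect_fovea()], [segment_fluid()]) on the
#' intensity images, exercising the full evaluation pipeline from pixels.
#' Predicted post-therapeutic scans additionally get structural-continuity
#' quality flags.
#'
#' @param cohort an [generate_cohort()] result.
#' @param backend `"mask"` or `"image"`.
#' @param config [inference_config()] for the image backend.
#' @param min_gap_columns passed to [continuity_flags()].
#' @return Data frame with one row per (pair, role): `pair_id`, `role`,
#'   `fovea_x`, `crt`, `max_thickness`, `srf_area`, `irc_area`, and the three
#'   discontinuity flags.
#' @export
evaluate_cohort <- function(cohort, backend = c("mask", "image"),
                            config = inference_config(),
                            min_gap_columns = 3L) {
  stopifnot(inherits(cohort, "oct_cohort"))
  backend <- match.arg(backend)
  rows <- list()
  for (i in seq_along(cohort$pairs)) {
    for (role in c("pre", "post_real", "post_predicted")) {
      sc <- cohort$pairs[[i]][[role]]
      meas <- if (backend == "mask") {
        list(fovea_x = sc$fovea_x, truth = sc$truth,
             strat = sc$strat_mask)
      } else {
        inf <- infer_scene(sc$image, config)
        list(fovea_x = inf$fovea_x, truth = inf$truth,
             strat = inf$strat_mask)
      }
      fl <- continuity_flags(meas$strat, min_gap_columns)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = i, role = role, fovea_x = meas$fovea_x,
        crt = meas$truth$crt, max_thickness = meas$truth$max_thickness,
        srf_area = meas$truth$srf_area, irc_area = meas$truth$irc_area,
        neuroepithelium_discontinuity = fl$neuroepithelium_discontinuity,
        rpe_discontinuity = fl$rpe_discontinuity,
        entire_discontinuity = fl$entire_discontinuity)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the full structural-evaluation report
#'
#' Takes per-scan measurement rows (as from [evaluate_cohort()], or read from
#' CSV) and assembles, per anatomical quantity: the synthetic-vs-real trend
#' cross-tabulation with its accuracy and tie-zone count, presence metrics
#' for the fluid areas, the normality-gated paired comparison of predicted vs
#' gold post-therapeutic values, and the Bland-Altman agreement summary. A
#' quality section counts discontinuity flags on the predicted scans and the
#' resulting qualified proportion. Pairs missing any of the three roles are
#' excluded and counted.
#'
#' @param measurements data frame with columns `pair_id`, `role` (levels
#'   `pre`, `post_real`, `post_predicted`), the four quantities, and
#'   optionally the discontinuity flag columns.
#' @param rule the [trend_rule()] applied to both the predicted and the real
#'   trends.
#' @return An object of class `oct_report`.
#' @export
build_report <- function(measurements, rule = trend_rule()) {
  need <- c("pair_id", "role", "crt", "max_thickness", "srf_area", "irc_area")
  if (!all(need %in% names(measurements)))
    stopf("measurements needs columns %s", paste(need, collapse = ", "))
  roles <- c("pre", "post_real", "post_predicted")
  wide <- lapply(roles, function(r) {
    m <- measurements[measurements$role == r, , drop = FALSE]
    m[!duplicated(m$pair_id), , drop = FALSE]
  })
  names(wide) <- roles
  complete <- Reduce(intersect, lapply(wide, function(m) m$pair_id))
  n_input <- length(unique(measurements$pair_id))
  excluded <- setdiff(unique(measurements$pair_id), complete)
  if (length(excluded))
    warning(sprintf("%d pair(s) missing a role were excluded",
                    length(excluded)), call. = FALSE)
  wide <- lapply(wide, function(m) {
    m <- m[match(complete, m$pair_id), , drop = FALSE]
    m
  })

  qi <- quantity_info()
  quantities <- list()
  for (k in seq_len(nrow(qi))) {
    q <- qi$quantity[k]; fluid <- qi$is_fluid[k]
    pre <- wide$pre[[q]]; real <- wide$post_real[[q]]
    pred <- wide$post_predicted[[q]]
    lab <- function(post) vapply(seq_along(pre), function(i) {
      classify_trend(pre[i], post[i], rule, is_fluid = fluid)$value
    }, character(1L))
    flagged <- vapply(seq_along(pre), function(i) {
      classify_trend(pre[i], pred[i], rule, is_fluid = fluid)$adjudication_needed ||
        classify_trend(pre[i], real[i], rule, is_fluid = fluid)$adjudication_needed
    }, logical(1L))
    tab <- build_trend_table(lab(pred), lab(real))
    entry <- list(
      trend_table = tab,
      accuracy = table_accuracy(tab),
      tie_zone_pairs = sum(flagged),
      paired_stats = paired_comparison(pred, real),
      bland_altman = bland_altman(pred, real)
    )
    if (fluid) {
      pres <- function(a) ifelse(classify_presence(a), "present", "absent")
      ptab <- build_trend_table(pres(pred), pres(real),
                                label_set = c("absent", "present"))
      entry$presence_table <- ptab
      entry$presence_metrics <- binary_metrics(ptab, "present")
    }
    quantities[[q]] <- entry
  }

  quality <- NULL
  flag_cols <- c("neuroepithelium_discontinuity", "rpe_discontinuity",
                 "entire_discontinuity")
  if (all(flag_cols %in% names(measurements))) {
    mp <- wide$post_predicted
    n <- nrow(mp)
    unq <- mp$neuroepithelium_discontinuity | mp$rpe_discontinuity |
      mp$entire_discontinuity
    quality <- list(
      n_predicted = n,
      n_unqualified = sum(unq),
      n_neuroepithelium = sum(mp$neuroepithelium_discontinuity),
      n_rpe = sum(mp$rpe_discontinuity),
      n_entire = sum(mp$entire_discontinuity),
      qualified_pct = qualified_proportion(n - sum(unq), n)
    )
  }

  structure(list(
    n_pairs = length(complete),
    n_input_pairs = n_input,
    n_excluded = length(excluded),
    excluded_pairs = excluded,
    rule = rule,
    quality = quality,
    quantities = quantities
  ), class = "oct_report")
}

#' @export
print.oct_report <- function(x, ...) {
  cat(sprintf("<oct_report> %d pairs (%d excluded)\n",
              x$n_pairs, x$n_excluded))
  if (!is.null(x$quality))
    cat(sprintf("  quality: %d/%d qualified (%.2f%%)\n",
                x$quality$n_predicted - x$quality$n_unqualified,
                x$quality$n_predicted, x$quality$qualified_pct))
  for (q in names(x$quantities)) {
    e <- x$quantities[[q]]
    cat(sprintf("  %s: trend accuracy %.3f (%d tie-zone), bias %.3f, %.0f%% in LoA\n",
                q, e$accuracy, e$tie_zone_pairs, e$bland_altman$bias,
                100 * e$bland_altman$within_loa_fraction))
  }
  invisible(x)
}

report_to_list <- function(x) {
  out <- list(
    n_pairs = x$n_pairs, n_excluded = x$n_excluded,
    rule = unclass(x$rule), quality = x$quality,
    quantities = lapply(x$quantities, function(e) {
      r <- list(trend_table = unclass(e$trend_table),
                accuracy = e$accuracy,
                tie_zone_pairs = e$tie_zone_pairs,
                paired_stats = unclass(e$paired_stats),
                bland_altman = unclass(e$bland_altman))
      if (!is.null(e$presence_metrics)) {
        bm <- e$presence_metrics
        r$presence_table <- unclass(e$presence_table)
        r$presence_metrics <- list(
          accuracy = bm$accuracy$value,
          sensitivity = bm$sensitivity$value,
          specificity = bm$specificity$value,
          sensitivity_ci = bm$sensitivity$ci,
          specificity_ci = bm$specificity$ci)
      }
      r
    })
  )
  out
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (machine-readable), one CSV per trend/presence table
#' under `tables/`, and a plain-text `summary.txt`.
#'
#' @param report an [build_report()] result.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "oct_report"))
  dir.create(file.path(dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  for (q in names(report$quantities)) {
    e <- report$quantities[[q]]
    utils::write.csv(as.data.frame(unclass(e$trend_table)),
                     file.path(dir, "tables", paste0(q, "_trend.csv")))
    if (!is.null(e$presence_table))
      utils::write.csv(as.data.frame(unclass(e$presence_table)),
                       file.path(dir, "tables", paste0(q, "_presence.csv")))
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  for (q in names(report$quantities)) {
    cat("\n==", q, "==\n")
    print(unclass(report$quantities[[q]]$trend_table))
    print(report$quantities[[q]]$paired_stats)
    print(report$quantities[[q]]$bland_altman)
    if (!is.null(report$quantities[[q]]$presence_metrics))
      print(report$quantities[[q]]$presence_metrics)
  }
  invisible(dir)
}
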