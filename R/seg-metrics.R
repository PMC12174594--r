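#' Per-pixel confusion matrix between a gold and a predicted mask
#'
#' @param gold_mask,pred_mask integer matrices of identical dimensions with
#'   labels in `0:(K - 1)`.
#' @param K number of classes (default 3).
#' @return An object of class `pixel_confusion`: a `K x K` integer matrix,
#'   rows = gold class, columns = predicted class.
#' @export
pixel_confusion <- function(gold_mask, pred_mask, K = 3L) {
  if (!all(dim(gold_mask) == dim(pred_mask)))
    stopf("gold and predicted masks have different dimensions")
  if (any(gold_mask < 0 | gold_mask >= K | pred_mask < 0 | pred_mask >= K))
    stopf("mask labels must lie in 0..%d", K - 1L)
  lv <- 0:(K - 1L)
  counts <- table(factor(gold_mask, levels = lv),
                  factor(pred_mask, levels = lv))
  m <- matrix(as.integer(counts), K, K,
              dimnames = list(gold = lv, predicted = lv))
  structure(m, class = c("pixel_confusion", "matrix"))
}

#' Per-class segmentation metrics from a pixel confusion
#'
#' Computes, for every class `c`: recall `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' intersection-over-union `TP/(TP+FP+FN)`, and Dice `2TP/(2TP+FP+FN)`.
#' A class absent from both masks has every metric undefined (`NA`) and is
#' excluded from the macro average; a metric whose own denominator is zero is
#' likewise `NA`. The macro row is the unweighted mean over classes for which
#' the metric is defined.
#'
#' @param conf a [pixel_confusion()].
#' @return An object of class `class_metrics`: a data frame with one row per
#'   class plus a `"macro"` row and columns `recall`, `precision`, `iou`,
#'   `dice`.
#' @export
class_metrics <- function(conf) {
  stopifnot(inherits(conf, "pixel_confusion"))
  K <- nrow(conf)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  df <- data.frame(
    class = 0:(K - 1L),
    recall = safe_div(tp, tp + fn),
    precision = safe_div(tp, tp + fp),
    iou = safe_div(tp, tp + fp + fn),
    dice = safe_div(2 * tp, 2 * tp + fp + fn)
  )
  absent <- tp + fn + fp == 0
  df[absent, c("recall", "precision", "iou", "dice")] <- NA_real_
  macro <- data.frame(class = NA_integer_,
                      recall = mean(df$recall, na.rm = TRUE),
                      precision = mean(df$precision, na.rm = TRUE),
                      iou = mean(df$iou, na.rm = TRUE),
                      dice = mean(df$dice, na.rm = TRUE))
  out <- rbind(df, macro)
  rownames(out) <- c(paste0("class_", 0:(K - 1L)), "macro")
  structure(out, class = c("class_metrics", "data.frame"),
            macro_weighting = "unweighted over defined classes")
}

#' Score one or more gold/predicted mask pairs
#'
#' Convenience wrapper producing a metrics table shaped like the standard
#' per-stratum evaluation tables: one block of per-class rows (plus macro) per
#' named stratum. Pairs within a stratum are pooled at the pixel level before
#' metrics are computed.
#'
#' @param pairs a list of `list(gold, pred)` mask pairs, or a named list of
#'   such lists (one element per stratum).
#' @param K number of classes.
#' @return A data frame with columns `stratum`, `class`, `recall`,
#'   `precision`, `iou`, `dice`.
#' @export
segmentation_table <- function(pairs, K = 3L) {
  if (length(pairs) && is.list(pairs[[1L]]) && !is.null(pairs[[1L]]$gold))
    pairs <- list(all = pairs)
  blocks <- lapply(names(pairs), function(stratum) {
    confs <- lapply(pairs[[stratum]], function(p)
      unclass(pixel_confusion(p$gold, p$pred, K)))
    pooled <- Reduce(`+`, confs)
    pooled <- structure(pooled, class = c("pixel_confusion", "matrix"))
    cm <- class_metrics(pooled)
    cbind(stratum = stratum, class = rownames(cm),
          as.data.frame(cm)[, c("recall", "precision", "iou", "dice")])
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
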