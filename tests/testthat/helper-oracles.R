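# Independent brute-force oracles used across tests. These deliberately use
# naive loops / set operations rather than the package's vectorized code.

# Pixel counts of each lesion label by exhaustive looping.
brute_lesion_counts <- function(lesion_mask) {
  srf <- 0L; irc <- 0L
  for (r in seq_len(nrow(lesion_mask))) {
    for (cc in seq_len(ncol(lesion_mask))) {
      v <- lesion_mask[r, cc]
      if (v == 1L) srf <- srf + 1L
      if (v == 2L) irc <- irc + 1L
    }
  }
  c(srf = srf, irc = irc)
}

# Rasterized ellipse pixel count by exhaustive integer-pixel test.
brute_ellipse_area <- function(cx, cy, ax, ay, width, height) {
  n <- 0L
  for (x in 0:(width - 1L)) {
    for (y in 0:(height - 1L)) {
      if ((x - cx)^2 / ax^2 + (y - cy)^2 / ay^2 <= 1) n <- n + 1L
    }
  }
  n
}

# Per-class metrics from logical set operations on flattened masks.
brute_class_metrics <- function(gold, pred, cls) {
  g <- as.vector(gold) == cls
  p <- as.vector(pred) == cls
  tp <- sum(g & p); fp <- sum(!g & p); fn <- sum(g & !p)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  list(recall = div(tp, tp + fn),
       precision = div(tp, tp + fp),
       iou = div(tp, tp + fp + fn),
       dice = div(2 * tp, 2 * tp + fp + fn))
}

# Brute-force anatomy from masks: per-column class-1 count, at fovea / max.
brute_thickness <- function(strat_mask, col) {
  n <- 0L
  for (r in seq_len(nrow(strat_mask))) if (strat_mask[r, col] == 1L) n <- n + 1L
  n
}

brute_truth <- function(scene) {
  W <- ncol(scene$strat_mask)
  prof <- vapply(seq_len(W), function(j) brute_thickness(scene$strat_mask, j),
                 integer(1L))
  col <- trunc(scene$fovea_x * (W - 1L) + 0.5) + 1L
  areas <- brute_lesion_counts(scene$lesion_mask)
  list(crt = prof[col], max_thickness = max(prof),
       srf_area = unname(areas["srf"]), irc_area = unname(areas["irc"]))
}

# Small random label mask.
random_mask <- function(nr, nc, K = 3L) {
  matrix(sample(0:(K - 1L), nr * nc, replace = TRUE), nr, nc)
}

# A compact edematous scene used by several tests.
demo_params <- function(speckle = 0.15, ...) {
  scene_params(width = 160L, height = 128L, ilm = 36, rpe = 86, choroid = 114,
               fovea_x = 0.5, fovea_depth = 12,
               cysts = data.frame(cx = 55, cy = 60, ax = 7, ay = 5),
               srf_pockets = data.frame(x_start = 90, x_end = 130,
                                        max_height = 9),
               speckle_level = speckle, ...)
}
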