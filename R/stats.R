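#' Normality-gated paired comparison
#'
#' Applies the study's statistical protocol for predicted-vs-gold agreement:
#' a Shapiro-Wilk test on the paired differences decides between a paired
#' t-test (differences normal, `shapiro_p >= alpha`) and a two-sided Wilcoxon
#' signed-rank test (otherwise). When every difference is zero neither the
#' Shapiro test nor either branch is defined; the result then reports
#' `p_value = 1` with `degenerate = TRUE`.
#'
#' @param pred,gold paired measurement vectors of equal length (>= 3).
#' @param alpha normality-gate level (default 0.05).
#' @return An object of class `paired_stats`: `n`, `mean_pred`, `sd_pred`,
#'   `mean_gold`, `sd_gold`, `shapiro_p`, `test_used` (`"paired-t"`,
#'   `"wilcoxon"`, or `NA` for degenerate data), `p_value`, `degenerate`.
#' @export
paired_comparison <- function(pred, gold, alpha = 0.05) {
  if (length(pred) != length(gold)) stopf("pred and gold differ in length")
  n <- length(pred)
  if (n < 3L) stopf("need at least 3 pairs")
  d <- pred - gold
  out <- list(n = n,
              mean_pred = mean(pred), sd_pred = stats::sd(pred),
              mean_gold = mean(gold), sd_gold = stats::sd(gold),
              shapiro_p = NA_real_, test_used = NA_character_,
              p_value = NA_real_, degenerate = FALSE)
  if (all(d == 0) || stats::sd(d) == 0) {
    # constant differences: Shapiro undefined; with all-zero differences the
    # samples are identical and no test can reject
    out$degenerate <- TRUE
    out$p_value <- 1
    return(structure(out, class = "paired_stats"))
  }
  out$shapiro_p <- stats::shapiro.test(d)$p.value
  if (out$shapiro_p >= alpha) {
    out$test_used <- "paired-t"
    out$p_value <- stats::t.test(d)$p.value
  } else {
    out$test_used <- "wilcoxon"
    out$p_value <- suppressWarnings(stats::wilcox.test(d)$p.value)
  }
  structure(out, class = "paired_stats")
}

#' @export
print.paired_stats <- function(x, ...) {
  cat(sprintf(
    "<paired_stats> n = %d | pred %.2f (%.2f), gold %.2f (%.2f)\n",
    x$n, x$mean_pred, x$sd_pred, x$mean_gold, x$sd_gold))
  if (x$degenerate) cat("  degenerate (all differences equal); p = 1\n")
  else cat(sprintf("  Shapiro p = %.4g -> %s, p = %.4g\n",
                   x$shapiro_p, x$test_used, x$p_value))
  invisible(x)
}

#' Bland-Altman agreement between predicted and gold measurements
#'
#' Differences `d = pred - gold`; bias is their mean and the 95\% limits of
#' agreement are `bias +- 1.96 * sd(d)` (sample sd). Also reports the
#' fraction of differences inside the closed LoA interval. With `sd(d) = 0`
#' the limits degenerate to the bias and the fraction is 1.
#'
#' @param pred,gold paired measurement vectors of equal length (>= 2).
#' @return An object of class `bland_altman`: `n`, `bias`, `loa_low`,
#'   `loa_high`, `within_loa_fraction`.
#' @export
bland_altman <- function(pred, gold) {
  if (length(pred) != length(gold)) stopf("pred and gold differ in length")
  if (length(pred) < 2L) stopf("need at least 2 pairs")
  d <- pred - gold
  bias <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(structure(list(n = length(d), bias = bias, loa_low = bias,
                          loa_high = bias, within_loa_fraction = 1),
                     class = "bland_altman"))
  }
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  structure(list(n = length(d), bias = bias, loa_low = lo, loa_high = hi,
                 within_loa_fraction = mean(d >= lo & d <= hi)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias %.3f, LoA [%.3f, %.3f], %.1f%% within\n",
    x$n, x$bias, x$loa_low, x$loa_high, 100 * x$within_loa_fraction))
  invisible(x)
}
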