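#' Relative-change rule for treatment-response trends
#'
#' A quantity has "increased" when the post-therapeutic value exceeds the
#' pre-therapeutic value by more than `rel_threshold` (default 10\%), and
#' "decreased" when the pre-therapeutic value exceeds the post-therapeutic
#' value by the same relative margin (i.e. `post < pre / (1 + threshold)`) —
#' the thresholds are deliberately asymmetric, mirroring the literal clinical
#' rule. Pairs inside the residual band fall in the tie zone: they are the
#' cases a human specialist would adjudicate, so they carry an
#' `adjudication_needed` flag and are labeled per `tie_policy`.
#'
#' @param rel_threshold relative threshold in (0, 1); default 0.10.
#' @param tie_policy `"no_change"` (label tie-zone cases `no_change`, flagged)
#'   or `"error"` (refuse to classify tie-zone cases).
#' @return An object of class `trend_rule`.
#' @export
trend_rule <- function(rel_threshold = 0.10,
                       tie_policy = c("no_change", "error")) {
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stopf("rel_threshold must lie in (0, 1)")
  structure(list(rel_threshold = rel_threshold,
                 tie_policy = match.arg(tie_policy)),
            class = "trend_rule")
}

#' Classify the treatment trend of one quantity
#'
#' Compares a post-therapeutic value against its pre-therapeutic baseline
#' under a [trend_rule()]. For fluid quantities, absence both before and after
#' treatment (`pre == 0 && post == 0`) is `no_change` outright, with no
#' adjudication flag; a fluid appearing from zero is an `increase`.
#'
#' @param pre_value,post_value non-negative measurements.
#' @param rule a [trend_rule()].
#' @param is_fluid `TRUE` for SRF/IRC areas (activates the both-zero rule).
#' @return A `trend_label` list: `value` in
#'   `c("decrease", "no_change", "increase")` and `adjudication_needed`.
#' @export
classify_trend <- function(pre_value, post_value, rule = trend_rule(),
                           is_fluid = FALSE) {
  if (!is.finite(pre_value) || !is.finite(post_value) ||
        pre_value < 0 || post_value < 0)
    stopf("trend inputs must be finite and non-negative")
  th <- 1 + rule$rel_threshold
  lab <- function(value, flag = FALSE)
    structure(list(value = value, adjudication_needed = flag),
              class = "trend_label")
  if (is_fluid && pre_value == 0 && post_value == 0) return(lab("no_change"))
  if (post_value > pre_value * th) return(lab("increase"))
  if (pre_value > post_value * th) return(lab("decrease"))
  if (rule$tie_policy == "error")
    stopf("pair (%g, %g) falls in the tie zone", pre_value, post_value)
  lab("no_change", flag = TRUE)
}

#' Dichotomize fluid presence
#'
#' @param area measured fluid area (>= 0).
#' @param min_area presence threshold; an area is "present" only when strictly
#'   greater than `min_area` (default 0).
#' @return Logical.
#' @export
classify_presence <- function(area, min_area = 0) {
  if (any(area < 0)) stopf("areas must be >= 0")
  area > min_area
}

#' Cross-tabulate synthetic vs real trend labels
#'
#' @param synthetic,real character vectors of labels (synthetic-vs-pre trend
#'   in rows, real-vs-pre trend in columns).
#' @param label_set the ordered label set; both 2-level
#'   (`c("decrease", "increase")`) and 3-level sets are used in practice.
#' @return An object of class `trend_table`: an integer matrix with row/column
#'   margins available via [margin_totals()].
#' @export
build_trend_table <- function(synthetic, real,
                              label_set = c("decrease", "no_change",
                                            "increase")) {
  if (length(synthetic) == 0L || length(real) == 0L)
    stopf("cannot tabulate an empty pair list")
  if (length(synthetic) != length(real))
    stopf("synthetic and real label vectors differ in length")
  unknown <- setdiff(unique(c(synthetic, real)), label_set)
  if (length(unknown))
    stopf("unknown trend label(s): %s", paste(unknown, collapse = ", "))
  counts <- table(factor(synthetic, levels = label_set),
                  factor(real, levels = label_set))
  m <- matrix(as.integer(counts), length(label_set), length(label_set),
              dimnames = list(synthetic = label_set, real = label_set))
  structure(m, class = c("trend_table", "matrix"))
}

# Build a trend_table directly from printed counts.
trend_table_from_counts <- function(counts, labels) {
  m <- matrix(as.integer(counts), length(labels), length(labels),
              byrow = TRUE, dimnames = list(synthetic = labels, real = labels))
  structure(m, class = c("trend_table", "matrix"))
}

#' Row and column margins of a trend table
#'
#' @param table a [build_trend_table()] result.
#' @return List with `row_totals`, `col_totals`, `total`.
#' @export
margin_totals <- function(table) {
  stopifnot(inherits(table, "trend_table"))
  list(row_totals = rowSums(table), col_totals = colSums(table),
       total = sum(table))
}

#' Agreement proportion of a trend table
#'
#' The accuracy of trend prediction: the proportion of pairs whose synthetic
#' and real trends agree (trace over total).
#'
#' @param table a [build_trend_table()] result.
#' @return Fraction in \[0, 1\].
#' @export
table_accuracy <- function(table) {
  stopifnot(inherits(table, "trend_table"))
  n <- sum(table)
  if (n == 0L) stopf("trend table is empty")
  sum(diag(table)) / n
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles:
#' `low = qbeta(alpha/2, x, n - x + 1)`, `high = qbeta(1 - alpha/2, x + 1,
#' n - x)`, with `low = 0` when `x = 0` and `high = 1` when `x = n`. For
#' `x = 0` the upper bound has the closed form `1 - (alpha/2)^(1/n)`.
#'
#' @param successes,trials binomial outcome, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials < 1L) stopf("trials must be >= 1")
  if (successes < 0L || successes > trials)
    stopf("successes must lie in 0..trials")
  if (level <= 0 || level >= 1) stopf("level must lie in (0, 1)")
  alpha <- 1 - level
  low <- if (successes == 0L) 0
         else stats::qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1
          else stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(low = low, high = high)
}

#' Accuracy, sensitivity, and specificity of a 2x2 trend/presence table
#'
#' Rows are the synthetic (predicted) outcome, columns the real outcome.
#' Sensitivity is computed over real positives, specificity over real
#' negatives; each carries an exact [clopper_pearson()] confidence interval.
#' When the real column for a metric is empty the metric is `NA` and its CI is
#' omitted.
#'
#' @param table a 2x2 [build_trend_table()] result.
#' @param positive_label row/column name of the positive outcome.
#' @param level confidence level for the intervals.
#' @return An object of class `binary_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, each with `ci`.
#' @export
binary_metrics <- function(table, positive_label, level = 0.95) {
  stopifnot(inherits(table, "trend_table"))
  if (!all(dim(table) == 2L)) stopf("binary_metrics needs a 2x2 table")
  if (!positive_label %in% rownames(table))
    stopf("positive_label '%s' not in table labels", positive_label)
  n <- sum(table)
  if (n == 0L) stopf("table is empty")
  pos <- positive_label
  neg <- setdiff(rownames(table), pos)
  tp <- table[pos, pos]; tn <- table[neg, neg]
  fp <- table[pos, neg]; fn <- table[neg, pos]
  real_pos <- tp + fn; real_neg <- tn + fp
  metric <- function(x, m) {
    if (m == 0L) return(list(value = NA_real_, ci = NULL, n = 0L))
    list(value = x / m, ci = clopper_pearson(x, m, level), n = m)
  }
  structure(list(
    accuracy = metric(tp + tn, n),
    sensitivity = metric(tp, real_pos),
    specificity = metric(tn, real_neg),
    positive_label = pos, level = level
  ), class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  fmt <- function(m, name) {
    if (is.na(m$value)) return(sprintf("  %s: undefined (no cases)\n", name))
    ci <- if (is.null(m$ci)) "" else
      sprintf(" (%.0f%% CI %.2f-%.2f)", 100 * x$level, m$ci[1L], m$ci[2L])
    sprintf("  %s: %.2f%s\n", name, m$value, ci)
  }
  cat("<binary_metrics> positive =", x$positive_label, "\n")
  cat(fmt(x$accuracy, "accuracy"),
      fmt(x$sensitivity, "sensitivity"),
      fmt(x$specificity, "specificity"), sep = "")
  invisible(x)
}
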