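# Evaluation: AUROC and fold-level aggregation, stratified metrics,
# probability histograms, and the screening trade-off analysis
# (false-negative percentage vs true-negative percentage vs sensitivity)
# with operating-point selection.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pairwise concordance: the probability that
#' a random positive receives a higher score than a random negative, with
#' ties counted one half.
#'
#' @param probability numeric scores, or a data.frame of prediction records
#'   with `probability` and `label` columns.
#' @param label 0/1 labels (ignored when a data.frame is given).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(probability, label = NULL) {
  if (is.data.frame(probability)) {
    label <- probability$label
    probability <- probability$probability
  }
  if (any(!is.finite(probability))) stopf("probabilities must be finite")
  label <- as.integer(label)
  n_pos <- sum(label == 1)
  n_neg <- sum(label == 0)
  if (n_pos == 0 || n_neg == 0) stopf("AUROC requires both classes")
  r <- rank(probability)
  (sum(r[label == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean AUROC with a t-based confidence interval across folds
#'
#' @param values per-fold AUROC values (length >= 2).
#' @param conf confidence level (default 0.95).
#' @return list with `mean`, `ci` (lower, upper), `sd`, `n`.
#' @export
mean_auroc_ci <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2) stopf("need at least two folds for a confidence interval")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  list(mean = m, ci = c(m - half, m + half), sd = s, n = n)
}

#' Stratified AUROC by a metadata key
#'
#' Computes the AUROC within each level of `scanner`, `site` or `mode`.
#' Strata in which only one class is present are reported as undefined
#' (`NA` with `defined = FALSE`) rather than silently dropped.
#'
#' @param records prediction records (see [predict_cases()]).
#' @param key one of `"scanner"`, `"site"`, `"mode"`.
#' @return data.frame with `group`, `n`, `n_pos`, `auroc`, `defined`.
#' @export
stratified_auroc <- function(records, key = c("scanner", "site", "mode")) {
  key <- match.arg(key)
  out <- do.call(rbind, lapply(split(records, records[[key]]), function(d) {
    ok <- length(unique(d$label)) == 2
    data.frame(group = as.character(d[[key]][1]), n = nrow(d),
               n_pos = sum(d$label == 1),
               auroc = if (ok) auroc(d$probability, d$label) else NA_real_,
               defined = ok)
  }))
  rownames(out) <- NULL
  out
}

#' Screening trade-off curve
#'
#' Sweeps every distinct predicted probability as a decision threshold
#' (predict positive iff probability >= threshold) and reports, per
#' threshold, the false-negative percentage (FN / total cases x 100), the
#' true-negative percentage (TN / total x 100), and sensitivity
#' (TP / (TP + FN)). A final `Inf`-threshold row gives the all-negative
#' operating point. FN% is non-decreasing and sensitivity non-increasing
#' in the threshold.
#'
#' @param records prediction records with both classes present.
#' @return data.frame of class `tradeoff_curve` with columns `threshold`,
#'   `fn_pct`, `tn_pct`, `sensitivity`.
#' @export
tradeoff_curve <- function(records) {
  p <- records$probability
  y <- as.integer(records$label)
  if (length(unique(y)) < 2) stopf("trade-off analysis requires both classes")
  n <- length(y)
  n_pos <- sum(y == 1)
  thr <- c(sort(unique(p)), Inf)
  rows <- vapply(thr, function(t) {
    pred <- p >= t
    fn <- sum(y == 1 & !pred)
    tn <- sum(y == 0 & !pred)
    c(threshold = t, fn_pct = 100 * fn / n, tn_pct = 100 * tn / n,
      sensitivity = (n_pos - fn) / n_pos)
  }, numeric(4))
  out <- as.data.frame(t(rows))
  class(out) <- c("tradeoff_curve", "data.frame")
  out
}

#' Select a screening operating point
#'
#' Among curve points whose false-negative percentage does not exceed
#' `target_fn_pct`, returns the one ruling out the most cases (maximal
#' true-negative percentage; lowest threshold on ties). Errors when no
#' point satisfies the bound.
#'
#' @param curve a [tradeoff_curve()].
#' @param target_fn_pct admissible false-negative percentage.
#' @return single-row data.frame (an operating point).
#' @export
pick_operating_point <- function(curve, target_fn_pct) {
  ok <- curve[curve$fn_pct <= target_fn_pct, , drop = FALSE]
  if (nrow(ok) == 0) stopf("no operating point with FN%% <= %g", target_fn_pct)
  ok <- ok[order(-ok$tn_pct, ok$threshold), , drop = FALSE]
  ok[1, , drop = FALSE]
}

#' Per-class probability histogram
#'
#' Bins the predicted probabilities of each class over `[0, 1]` with
#' half-open bins (the last bin closed), so counts sum to the class sizes.
#'
#' @param records prediction records.
#' @param n_bins number of bins (>= 2).
#' @return list with `breaks` and a `counts` matrix (class x bin).
#' @export
probability_histogram <- function(records, n_bins = 20L) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  p <- records$probability
  y <- as.integer(records$label)
  bin <- pmin(floor(p * n_bins), n_bins - 1L) + 1L
  counts <- rbind(
    negative = tabulate(bin[y == 0], nbins = n_bins),
    positive = tabulate(bin[y == 1], nbins = n_bins)
  )
  colnames(counts) <- sprintf("[%.2f,%.2f%s", (0:(n_bins - 1)) / n_bins,
                              (1:n_bins) / n_bins,
                              c(rep(")", n_bins - 1), "]"))
  list(breaks = (0:n_bins) / n_bins, counts = counts)
}

#' Plot a trade-off curve
#'
#' FN% on the x-axis, TN% on the left axis, sensitivity on the right.
#'
#' @param x a `tradeoff_curve`.
#' @param ... passed to `plot`.
#' @export
plot.tradeoff_curve <- function(x, ...) {
  fin <- x[is.finite(x$threshold), ]
  graphics::plot(fin$fn_pct, fin$tn_pct, type = "s", xlab = "FN %",
                 ylab = "TN %", ...)
  graphics::par(new = TRUE)
  graphics::plot(fin$fn_pct, fin$sensitivity, type = "s", col = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4, col.axis = 2)
  graphics::mtext("sensitivity", side = 4, line = 2, col = 2)
  invisible(x)
}
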