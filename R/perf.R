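# Performance tracking for the deployed classifier: AUROC and average
# precision with percentile-bootstrap confidence intervals, weekly binned
# AUROC series, and the confusion matrix at a fixed recall operating point.
# AUROC and AP are computed by their defining rank formulas because the
# surveillance rules depend on their exact tie and step conventions.

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability a random positive outscores a random
#' negative, ties credited one half.
#'
#' @param scores numeric vector (any monotone transform of risk).
#' @param labels binary 0/1 vector.
#' @return AUROC in `[0, 1]`; errors when only one class is present.
#' @export
auroc <- function(scores, labels) {
  stop_if(length(scores) != length(labels), "scores/labels length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  stop_if(n_pos == 0 || n_neg == 0,
          "AUROC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-interpolated: \eqn{\sum_k (R_k - R_{k-1}) P_k} over thresholds in
#' descending score order. Tied scores enter as one threshold block.
#'
#' @inheritParams auroc
#' @return AP in `(0, 1]`; errors with no positives.
#' @export
average_precision <- function(scores, labels) {
  stop_if(length(scores) != length(labels), "scores/labels length mismatch")
  n_pos <- sum(labels == 1)
  stop_if(n_pos == 0, "average precision undefined: no positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # block boundaries where the score strictly drops
  last_of_block <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[last_of_block]
  fp <- cumsum(1 - y)[last_of_block]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Percentile bootstrap confidence interval of a statistic
#'
#' Resamples rows with replacement and takes the 2.5/97.5 percentiles of the
#' statistic. Resamples on which the statistic is undefined (e.g. a
#' single-class AUROC resample) are skipped and counted.
#'
#' @param stat_fn function of (scores, labels) -- or of one vector if
#'   `labels` is `NULL` -- returning a scalar.
#' @param scores numeric vector (or arbitrary data vector).
#' @param labels optional aligned binary vector.
#' @param n_boot number of resamples (default 1000).
#' @param seed integer seed.
#' @param probs interval percentiles (default `c(0.025, 0.975)`).
#' @return list: `low`, `high`, `n_skipped`.
#' @export
bootstrap_ci <- function(stat_fn, scores, labels = NULL, n_boot = 1000L,
                         seed = 1L, probs = c(0.025, 0.975)) {
  n <- length(scores)
  stop_if(n == 0, "empty data")
  stop_if(n_boot < 1, "n_boot must be at least 1")
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(
        if (is.null(labels)) stat_fn(scores[idx])
        else stat_fn(scores[idx], labels[idx]),
        error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- stats[!is.na(stats)]
  stop_if(length(ok) == 0, "all bootstrap resamples degenerate")
  qs <- quantile(ok, probs, names = FALSE, type = 7)
  list(low = qs[1], high = qs[2], n_skipped = sum(is.na(stats)))
}

#' Weekly binned model performance with bootstrap intervals
#'
#' Bins episodes into Monday-anchored weeks and evaluates AUROC with a
#' percentile-bootstrap 95% CI per bin. Bins containing a single outcome
#' class are reported with `NA` AUROC (flagged, not fatal); empty weeks in
#' the spanned range appear with `n = 0`.
#'
#' @param scores,labels aligned vectors.
#' @param timestamps aligned `POSIXct`/`Date` vector.
#' @param n_boot bootstrap resamples per bin (default 1000).
#' @param seed integer seed (bin `w` uses substream `seed + w`).
#' @param anchor optional week anchor date.
#' @return data.frame: `week`, `week_start`, `auroc`, `ci_lo`, `ci_hi`,
#'   `n`, `n_pos`.
#' @export
binned_performance <- function(scores, labels, timestamps, n_boot = 1000L,
                               seed = 1L, anchor = NULL) {
  stop_if(length(scores) != length(labels) ||
          length(scores) != length(timestamps), "inputs are not aligned")
  wb <- week_bins(timestamps, anchor)
  weeks <- 0:max(wb$week)
  rows <- lapply(weeks, function(w) {
    idx <- which(wb$week == w)
    out <- data.frame(week = w,
                      week_start = wb$anchor + 7 * w,
                      auroc = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      n = length(idx), n_pos = sum(labels[idx] == 1))
    if (length(idx) > 0 && out$n_pos > 0 && out$n_pos < length(idx)) {
      out$auroc <- auroc(scores[idx], labels[idx])
      ci <- bootstrap_ci(auroc, scores[idx], labels[idx],
                         n_boot = n_boot, seed = seed + w)
      out$ci_lo <- ci$low
      out$ci_hi <- ci$high
    }
    out
  })
  do.call(rbind, rows)
}

#' Confusion matrix at a fixed recall operating point
#'
#' Chooses the largest score threshold whose recall (sensitivity) reaches
#' `target_recall`, then tabulates the confusion counts at `score >=
#' threshold`.
#'
#' @param scores,labels aligned vectors; at least one positive.
#' @param target_recall required recall in `(0, 1]` (default 0.75).
#' @return list: `threshold`, `tp`, `fp`, `fn`, `tn`, `recall` (achieved),
#'   `precision`.
#' @export
confusion_at_recall <- function(scores, labels, target_recall = 0.75) {
  n_pos <- sum(labels == 1)
  stop_if(n_pos == 0, "no positives: recall target unreachable")
  stop_if(target_recall <= 0 || target_recall > 1,
          "target recall must lie in (0, 1]")
  pos_scores <- sort(scores[labels == 1], decreasing = TRUE)
  need <- ceiling(target_recall * n_pos)
  thr <- pos_scores[need]  # largest cut admitting >= `need` positives
  pred <- scores >= thr
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  list(threshold = thr, tp = tp, fp = fp, fn = fn, tn = tn,
       recall = tp / n_pos, precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Cohort performance summary
#'
#' AUROC and average precision with bootstrap 95% CIs, plus the confusion
#' matrix at a fixed recall.
#'
#' @inheritParams confusion_at_recall
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list: `auroc` (`point`, `low`, `high`), `average_precision`
#'   (same), `confusion` (see [confusion_at_recall()]), `n`, `n_pos`.
#' @export
performance_summary <- function(scores, labels, target_recall = 0.75,
                                n_boot = 1000L, seed = 1L) {
  ci_a <- bootstrap_ci(auroc, scores, labels, n_boot = n_boot, seed = seed)
  ci_p <- bootstrap_ci(average_precision, scores, labels, n_boot = n_boot,
                       seed = seed + 1L)
  list(
    auroc = list(point = auroc(scores, labels), low = ci_a$low,
                 high = ci_a$high),
    average_precision = list(point = average_precision(scores, labels),
                             low = ci_p$low, high = ci_p$high),
    confusion = confusion_at_recall(scores, labels, target_recall),
    n = length(labels), n_pos = sum(labels == 1))
}
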