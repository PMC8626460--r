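# Surveillance rules and the end-to-end monitoring pipeline. Importance and
# performance series are turned into per-week flags by persistence rules
# (k consecutive excluded bins), and the two flag sets are combined into the
# drift-type call: importance change without degradation is data drift;
# degradation without importance change points at concept drift (the model's
# decision making is unchanged, so the feature-outcome relationship must
# have moved); both together is data drift with degradation.

#' Flag weeks where a feature's importance share departs from baseline
#'
#' For each monitored bin, a null interval for a bin mean of that size is
#' built by resampling the pooled baseline shares (percentile bootstrap,
#' central `1 - alpha` interval). A feature is flagged at week `b` when its
#' bin mean falls outside the null interval, in a consistent direction, for
#' at least `k_consec` consecutive non-empty bins ending at `b`.
#'
#' @param series monitored-period importance series from [bin_importance()].
#' @param baseline_shares share matrix of the baseline (reference) period,
#'   same features; must be disjoint from the monitored period.
#' @param k_consec run length required before flagging (default 2).
#' @param n_boot bootstrap resamples for the null intervals (default 1000).
#' @param seed integer seed.
#' @param alpha two-sided exceedance level of the null interval (default
#'   0.01; small because ~18 features x many weeks are scanned jointly).
#' @return data.frame of flagged weeks: `feature`, `week`, `direction`
#'   (`"up"`/`"down"`), `mean`, `null_lo`, `null_hi`.
#' @export
flag_importance_drift <- function(series, baseline_shares, k_consec = 2L,
                                  n_boot = 1000L, seed = 1L, alpha = 0.01) {
  baseline_shares <- as.matrix(baseline_shares)
  stop_if(nrow(baseline_shares) == 0, "empty baseline")
  feats <- unique(series$feature)
  stop_if(!all(feats %in% colnames(baseline_shares)),
          "baseline shares do not cover the series' features")
  probs <- c(alpha / 2, 1 - alpha / 2)
  n0 <- nrow(baseline_shares)
  # null intervals per distinct bin size
  sizes <- sort(unique(series$n[series$n > 0]))
  null_int <- list()
  for (si in seq_along(sizes)) {
    nb <- sizes[si]
    boot <- with_seed(seed + si, {
      t(vapply(seq_len(n_boot), function(b)
        colMeans(baseline_shares[sample.int(n0, nb, replace = TRUE), ,
                                 drop = FALSE]),
        numeric(ncol(baseline_shares))))
    })
    null_int[[as.character(nb)]] <- apply(boot, 2, quantile, probs,
                                          names = FALSE)
  }
  flags <- list()
  for (f in feats) {
    sub <- series[series$feature == f & series$n > 0, , drop = FALSE]
    sub <- sub[order(sub$week), , drop = FALSE]
    if (nrow(sub) == 0) next
    lo <- hi <- numeric(nrow(sub))
    for (r in seq_len(nrow(sub))) {
      q <- null_int[[as.character(sub$n[r])]][, colnames(baseline_shares) == f]
      lo[r] <- q[1]; hi[r] <- q[2]
    }
    dir <- ifelse(sub$mean > hi, 1L, ifelse(sub$mean < lo, -1L, 0L))
    run <- 0L
    prev <- 0L
    for (r in seq_len(nrow(sub))) {
      run <- if (dir[r] == 0L) 0L else if (dir[r] == prev) run + 1L else 1L
      prev <- dir[r]
      if (dir[r] != 0L && run >= k_consec)
        flags[[length(flags) + 1L]] <- data.frame(
          feature = f, week = sub$week[r],
          direction = if (dir[r] > 0) "up" else "down",
          mean = sub$mean[r], null_lo = lo[r], null_hi = hi[r])
    }
  }
  if (length(flags) == 0)
    return(data.frame(feature = character(), week = integer(),
                      direction = character(), mean = numeric(),
                      null_lo = numeric(), null_hi = numeric()))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Flag weeks of sustained performance degradation
#'
#' A week is flagged when its AUROC bootstrap CI lies entirely below the
#' reference AUROC for at least `k_consec` consecutive defined bins ending
#' at that week (one-sided: only degradation triggers retraining concerns).
#'
#' @param series weekly performance series from [binned_performance()]
#'   restricted to the monitored period.
#' @param reference_auroc reference AUROC from a disjoint (baseline) period.
#' @param k_consec run length required before flagging (default 2).
#' @return data.frame of flagged weeks: `week`, `auroc`, `ci_hi`, `pooled`
#'   (always `FALSE` here; [run_monitoring()] appends a pooled-window row
#'   when the whole monitored window's CI sits below the reference).
#' @export
flag_performance_drift <- function(series, reference_auroc, k_consec = 2L) {
  sub <- series[!is.na(series$auroc), , drop = FALSE]
  stop_if(nrow(series) > 0 && nrow(sub) == 0,
          "all monitored bins have undefined AUROC")
  sub <- sub[order(sub$week), , drop = FALSE]
  below <- sub$ci_hi < reference_auroc
  run <- 0L
  keep <- logical(nrow(sub))
  for (r in seq_len(nrow(sub))) {
    run <- if (below[r]) run + 1L else 0L
    keep[r] <- below[r] && run >= k_consec
  }
  out <- sub[keep, c("week", "auroc", "ci_hi"), drop = FALSE]
  out$pooled <- logical(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify drift type from the two flag sets
#'
#' Pure rule table over a classification window: importance flags without
#' performance flags mean the covariate mix feeding the model changed while
#' discrimination held (`data_drift_no_degradation`); performance flags
#' without importance flags mean the model's decision making is unchanged
#' yet its ranking degrades, pointing at a changed feature-outcome
#' relationship (`concept_drift_suspected`); both mean
#' `data_drift_with_degradation`; neither, `stable`.
#'
#' @param importance_flags data.frame from [flag_importance_drift()].
#' @param performance_flags data.frame from [flag_performance_drift()].
#' @param window integer week range `c(first, last)` inclusive; `NULL` uses
#'   every flagged week.
#' @return one of `"stable"`, `"data_drift_no_degradation"`,
#'   `"concept_drift_suspected"`, `"data_drift_with_degradation"`.
#' @export
classify_drift <- function(importance_flags, performance_flags,
                           window = NULL) {
  in_window <- function(w) {
    if (is.null(window)) rep(TRUE, length(w))
    else w >= window[1] & w <= window[2]
  }
  imp <- nrow(importance_flags) > 0 &&
    any(in_window(importance_flags$week))
  perf <- nrow(performance_flags) > 0 &&
    any(in_window(performance_flags$week))
  if (imp && perf) "data_drift_with_degradation"
  else if (imp) "data_drift_no_degradation"
  else if (perf) "concept_drift_suspected"
  else "stable"
}

#' Run the full drift-surveillance pipeline
#'
#' simulate (or load) -> temporal split -> encode (frozen on train) -> fit
#' boosted trees -> Shapley attributions -> normalised weekly importance
#' series -> weekly AUROC series -> flags -> drift-type classification.
#' The pre-period test cohort is the baseline reference for both rules; the
#' during-period cohort is monitored. Performance degradation is checked
#' both weekly (persistence rule) and pooled over the classification
#' window, mirroring the pre/during cohort contrast: a small sustained drop
#' that weekly bins cannot resolve is still caught by the pooled interval.
#'
#' @param config named list. Either `scenario` (a `scenario_config`) or
#'   `episodes` (an episode table or CSV path; needs a `week`-derivable
#'   timestamp column). Optional entries with defaults:
#'   `train_weeks = 20`, `pre_weeks = 20` (temporal boundaries in weeks from
#'   the start), `hyperparams = list()`, `encoding_m = 10`,
#'   `background_size = 256`, `n_boot = 1000`, `k_consec = 2`,
#'   `alpha_importance = 0.01`, `target_recall = 0.75`,
#'   `classification_window_weeks = 8`, `out_dir = NULL`.
#' @param seed master integer seed; stage s uses substream `seed + s`.
#' @return a `drift_report` list: `classification`, `importance_flags`,
#'   `performance_flags`, `importance_series`, `performance_series`,
#'   `summary_pre` / `summary_during` ([performance_summary()]),
#'   `importance_delta`, `prevalence_shifts`, `new_category_events`,
#'   `provenance`.
#' @export
run_monitoring <- function(config, seed = 1L) {
  cfg <- modifyList(list(
    train_weeks = 20L, pre_weeks = 20L, hyperparams = list(),
    encoding_m = 10, background_size = 256L, n_boot = 1000L,
    k_consec = 2L, alpha_importance = 0.01, target_recall = 0.75,
    classification_window_weeks = 8L, out_dir = NULL), config)

  episodes <- if (!is.null(cfg$scenario)) {
    simulate_cohort(cfg$scenario, seed = seed)
  } else if (is.character(cfg$episodes)) {
    read_episodes(cfg$episodes)
  } else {
    stop_if(is.null(cfg$episodes), "config needs a scenario or episodes")
    cfg$episodes
  }
  start <- monday_floor(min(as.Date(episodes$timestamp, tz = "UTC")))
  b1 <- as.POSIXct(start, tz = "UTC") + cfg$train_weeks * 7 * 86400
  b2 <- as.POSIXct(start, tz = "UTC") + (cfg$train_weeks + cfg$pre_weeks) *
    7 * 86400
  split <- temporal_split(episodes, b1, b2)
  stop_if(nrow(split$train) == 0 || nrow(split$test_pre) == 0 ||
          nrow(split$test_during) == 0,
          "temporal split produced an empty cohort")

  enc_train <- encode_table(split$train, "fit", m = cfg$encoding_m)
  enc_pre <- encode_table(split$test_pre, enc_train$maps)
  enc_during <- encode_table(split$test_during, enc_train$maps)

  ens <- fit_tree_ensemble(enc_train$X, split$train$outcome,
                           cfg$hyperparams, seed = seed + 1L)
  bg <- sample_background(enc_train$X, cfg$background_size, seed = seed + 2L)

  att_pre <- explain_cohort(ens, enc_pre$X, bg)
  att_during <- explain_cohort(ens, enc_during$X, bg)
  shares_pre <- normalise_attributions(att_pre)$shares
  shares_during <- normalise_attributions(att_during)$shares

  ts_all <- c(split$test_pre$timestamp, split$test_during$timestamp)
  imp_series <- bin_importance(rbind(shares_pre, shares_during), ts_all,
                               n_boot = cfg$n_boot, seed = seed + 3L,
                               anchor = start)
  risk_pre <- predict_ensemble(ens, enc_pre$X, "risk")
  risk_during <- predict_ensemble(ens, enc_during$X, "risk")
  perf_series <- binned_performance(
    c(risk_pre, risk_during),
    c(split$test_pre$outcome, split$test_during$outcome),
    ts_all, n_boot = cfg$n_boot, seed = seed + 4L, anchor = start)

  during_start <- cfg$train_weeks + cfg$pre_weeks
  monitored_imp <- imp_series[imp_series$week >= during_start, , drop = FALSE]
  monitored_perf <- perf_series[perf_series$week >= during_start, ,
                                drop = FALSE]
  ref_auroc <- auroc(risk_pre, split$test_pre$outcome)

  imp_flags <- flag_importance_drift(monitored_imp, shares_pre,
                                     k_consec = cfg$k_consec,
                                     n_boot = cfg$n_boot, seed = seed + 5L,
                                     alpha = cfg$alpha_importance)
  perf_flags <- flag_performance_drift(monitored_perf, ref_auroc,
                                       k_consec = cfg$k_consec)
  last_week <- max(monitored_imp$week)
  window <- c(max(during_start, last_week - cfg$classification_window_weeks
                  + 1L), last_week)
  # pooled degradation check over the classification window: weekly bins can
  # lack power for a small but sustained drop, so the whole window's AUROC CI
  # is also compared against the reference (the pre/during cohort contrast)
  dw <- week_bins(split$test_during$timestamp, start)$week
  in_win <- dw >= window[1] & dw <= window[2]
  if (sum(in_win) > 1 &&
      length(unique(split$test_during$outcome[in_win])) == 2) {
    ci_win <- bootstrap_ci(auroc, risk_during[in_win],
                           split$test_during$outcome[in_win],
                           n_boot = cfg$n_boot, seed = seed + 8L)
    if (ci_win$high < ref_auroc)
      perf_flags <- rbind(perf_flags, data.frame(
        week = window[2],
        auroc = auroc(risk_during[in_win],
                      split$test_during$outcome[in_win]),
        ci_hi = ci_win$high, pooled = TRUE))
  }
  classification <- classify_drift(imp_flags, perf_flags, window)

  cat_cols <- setdiff(
    names(episodes)[vapply(episodes, is.character, logical(1))],
    c("episode_id", "cohort"))
  prev <- lapply(setNames(cat_cols, cat_cols), function(cc)
    prevalence_shift(c(split$test_pre[[cc]], split$test_during[[cc]]),
                     seq_len(nrow(split$test_pre)),
                     nrow(split$test_pre) + seq_len(nrow(split$test_during))))

  report <- structure(list(
    classification = classification,
    classification_window = window,
    importance_flags = imp_flags,
    performance_flags = perf_flags,
    importance_series = imp_series,
    performance_series = perf_series,
    reference_auroc = ref_auroc,
    summary_pre = performance_summary(risk_pre, split$test_pre$outcome,
                                      cfg$target_recall, cfg$n_boot,
                                      seed + 6L),
    summary_during = performance_summary(risk_during,
                                         split$test_during$outcome,
                                         cfg$target_recall, cfg$n_boot,
                                         seed + 7L),
    importance_delta = importance_delta(att_pre, att_during),
    prevalence_shifts = prev,
    new_category_events = enc_during$new_category_events,
    provenance = list(
      seed = seed,
      scenario_kind = if (!is.null(cfg$scenario)) cfg$scenario$kind else NA,
      n_train = nrow(split$train), n_pre = nrow(split$test_pre),
      n_during = nrow(split$test_during),
      hyperparams = modifyList(.default_hyperparams(), cfg$hyperparams),
      background_size = nrow(bg), n_boot = cfg$n_boot,
      k_consec = cfg$k_consec, alpha_importance = cfg$alpha_importance)
  ), class = "drift_report")
  if (!is.null(cfg$out_dir)) write_drift_report(report, cfg$out_dir)
  report
}

#' @export
print.drift_report <- function(x, ...) {
  cat("<drift_report>\n")
  cat("  classification:", x$classification, "(weeks",
      paste(x$classification_window, collapse = "-"), ")\n")
  cat("  AUROC pre:", round(x$summary_pre$auroc$point, 3),
      " during:", round(x$summary_during$auroc$point, 3), "\n")
  cat("  importance flags:", nrow(x$importance_flags),
      " performance flags:", nrow(x$performance_flags),
      " new categories:", nrow(x$new_category_events), "\n")
  invisible(x)
}

#' Persist a drift report as JSON plus tidy CSV tables
#'
#' @param report a `drift_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_drift_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(list(
    classification = report$classification,
    classification_window = report$classification_window,
    reference_auroc = report$reference_auroc,
    summary_pre = report$summary_pre,
    summary_during = report$summary_during,
    new_category_events = report$new_category_events,
    provenance = report$provenance
  ), file.path(dir, "drift_report.json"), auto_unbox = TRUE, digits = NA,
     na = "null", force = TRUE)
  write.csv(report$importance_series,
            file.path(dir, "importance_series.csv"), row.names = FALSE)
  write.csv(report$performance_series,
            file.path(dir, "performance_series.csv"), row.names = FALSE)
  write.csv(report$importance_flags,
            file.path(dir, "importance_flags.csv"), row.names = FALSE)
  write.csv(report$performance_flags,
            file.path(dir, "performance_flags.csv"), row.names = FALSE)
  write.csv(report$importance_delta,
            file.path(dir, "importance_delta.csv"), row.names = FALSE)
  for (nm in names(report$prevalence_shifts))
    write.csv(report$prevalence_shifts[[nm]],
              file.path(dir, paste0("prevalence_", nm, ".csv")),
              row.names = FALSE)
  invisible(dir)
}
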