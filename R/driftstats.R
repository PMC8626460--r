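# Drift-monitoring statistics on attribution matrices. The central quantity
# is the per-attendance normalised importance share: the absolute Shapley
# value of a feature divided by the sum of absolute Shapley values across
# all features for that attendance. Shares sum to one per attendance, so
# their cohort means are insensitive to rescalings of the outcome base rate
# that inflate every |phi| together -- the property that makes them a data
# drift signal rather than a prevalence signal.

#' Normalise attribution rows into per-attendance importance shares
#'
#' \eqn{s_i = |\phi_i| / \sum_j |\phi_j|} per row; the base value `phi0` is
#' not a feature and is excluded from the denominator. All-zero rows are
#' assigned the uniform share `1/d` and flagged degenerate.
#'
#' @param attributions an `attribution_matrix` (or bare numeric phi matrix).
#' @return list: `shares` (rows x features, each non-degenerate row summing
#'   to 1), `degenerate` logical vector.
#' @export
normalise_attributions <- function(attributions) {
  phi <- if (inherits(attributions, "attribution_matrix")) attributions$phi
         else as.matrix(attributions)
  stop_if(nrow(phi) == 0, "empty attribution matrix")
  a <- abs(phi)
  tot <- rowSums(a)
  degenerate <- tot == 0
  s <- a / ifelse(tot == 0, 1, tot)
  s[degenerate, ] <- 1 / ncol(phi)
  list(shares = s, degenerate = degenerate)
}

#' Weekly importance series with bootstrap intervals
#'
#' Bins per-attendance shares into Monday-anchored weeks and reports, per
#' feature per week, the mean share with a seeded percentile-bootstrap 95%
#' CI. Empty weeks in the spanned range are reported with `n = 0` and no
#' estimate.
#'
#' @param shares matrix of per-attendance shares (from
#'   [normalise_attributions()]), or any per-row statistic to track.
#' @param timestamps aligned `POSIXct`/`Date` vector.
#' @param n_boot bootstrap resamples per bin (default 1000).
#' @param seed integer seed (bin `w` uses substream `seed + w`).
#' @param anchor optional week anchor date.
#' @return data.frame: `feature`, `week`, `week_start`, `mean`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
bin_importance <- function(shares, timestamps, n_boot = 1000L, seed = 1L,
                           anchor = NULL) {
  shares <- as.matrix(shares)
  stop_if(nrow(shares) != length(timestamps),
          "timestamps do not align with share rows")
  stop_if(n_boot < 1, "n_boot must be at least 1")
  wb <- week_bins(timestamps, anchor)
  feats <- colnames(shares) %||% paste0("f", seq_len(ncol(shares)))
  rows <- list()
  for (w in 0:max(wb$week)) {
    idx <- which(wb$week == w)
    n <- length(idx)
    if (n == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feats, week = w, week_start = wb$anchor + 7 * w,
        mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, n = 0L)
      next
    }
    sub <- shares[idx, , drop = FALSE]
    mu <- colMeans(sub)
    boot_means <- with_seed(seed + w, {
      t(vapply(seq_len(n_boot), function(b)
        colMeans(sub[sample.int(n, n, replace = TRUE), , drop = FALSE]),
        numeric(ncol(sub))))
    })
    if (ncol(sub) == 1) boot_means <- matrix(boot_means, ncol = 1)
    lo <- apply(boot_means, 2, quantile, 0.025, names = FALSE)
    hi <- apply(boot_means, 2, quantile, 0.975, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = feats, week = w, week_start = wb$anchor + 7 * w,
      mean = unname(mu), ci_lo = lo, ci_hi = hi, n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-feature importance change between two periods
#'
#' Mean importance per feature in each period and the signed B - A
#' difference. `mode = "share"` averages normalised shares (deltas then sum
#' to zero across features); `mode = "raw_abs"` averages raw `|phi|`, which
#' retains base-rate scale effects.
#'
#' @param rows_A,rows_B `attribution_matrix` objects over the same features.
#' @param mode `"share"` (default) or `"raw_abs"`.
#' @return data.frame: `feature`, `mean_A`, `mean_B`, `delta`.
#' @export
importance_delta <- function(rows_A, rows_B, mode = c("share", "raw_abs")) {
  mode <- match.arg(mode)
  fa <- colnames(rows_A$phi); fb <- colnames(rows_B$phi)
  stop_if(!identical(fa, fb), "attribution matrices have different features")
  mean_of <- function(am) {
    if (mode == "share") colMeans(normalise_attributions(am)$shares)
    else colMeans(abs(am$phi))
  }
  a <- mean_of(rows_A); b <- mean_of(rows_B)
  data.frame(feature = fa, mean_A = unname(a), mean_B = unname(b),
             delta = unname(b - a))
}

#' Categorical prevalence shift between two periods
#'
#' Per-level prevalence in periods A and B and the B/A ratio. Levels absent
#' in A but present in B have no finite ratio and are flagged
#' `new_category`; levels absent in both are omitted.
#'
#' @param column character vector of level tokens.
#' @param mask_A,mask_B logical (or index) vectors selecting the two
#'   periods' rows.
#' @return data.frame: `level`, `prevalence_A`, `prevalence_B`, `ratio`,
#'   `new_category`.
#' @export
prevalence_shift <- function(column, mask_A, mask_B) {
  a <- as.character(column[mask_A])
  b <- as.character(column[mask_B])
  stop_if(length(a) == 0 || length(b) == 0, "empty period")
  levels <- sort(unique(c(a, b)))
  pa <- vapply(levels, function(l) mean(a == l, na.rm = TRUE), numeric(1))
  pb <- vapply(levels, function(l) mean(b == l, na.rm = TRUE), numeric(1))
  keep <- pa > 0 | pb > 0
  pa <- pa[keep]; pb <- pb[keep]; levels <- levels[keep]
  new <- pa == 0 & pb > 0
  data.frame(level = levels, prevalence_A = unname(pa),
             prevalence_B = unname(pb),
             ratio = ifelse(new, NA_real_, unname(pb / pa)),
             new_category = unname(new), row.names = NULL)
}
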