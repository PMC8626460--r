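# Shapley attribution of tree-ensemble margins under interventional
# (background-marginal) conditioning: the value of a coalition S is the mean
# model output with x's values on S and background values elsewhere. Two
# routes are provided -- a 2^d brute-force coalition enumeration usable on
# any black-box predictor, and the exact polynomial-cost per-tree engine --
# and they agree to floating-point tolerance, which the test suite enforces.

#' Sample a background (reference) set from a training matrix
#'
#' The background defines the "feature unknown" expectation baseline for all
#' attributions; by convention it is a fixed-seed sample of training rows.
#'
#' @param X training feature matrix.
#' @param size number of rows (default 256; capped at `nrow(X)`).
#' @param seed integer seed.
#' @return numeric matrix with the model's columns.
#' @export
sample_background <- function(X, size = 256L, seed = 1L) {
  X <- as.matrix(X)
  idx <- with_seed(seed, sample(nrow(X), min(size, nrow(X))))
  X[idx, , drop = FALSE]
}

#' Brute-force Shapley attribution by coalition enumeration
#'
#' Computes \deqn{\phi_i = \sum_{S \subseteq F \setminus \{i\}}
#' \frac{|S|!\,(d-|S|-1)!}{d!}\,[v(S \cup \{i\}) - v(S)]} with
#' \eqn{v(S)} the mean of `predict_fn` over the background rows with `x`
#' substituted on `S`. Exponential in the feature count (capped at 15);
#' intended as the independent oracle for [tree_shapley()], but works for
#' any row-vectorised predictor.
#'
#' @param predict_fn function taking a numeric matrix, returning one margin
#'   per row.
#' @param x single instance: numeric vector (NA = missing).
#' @param background numeric matrix of reference rows, columns as `x`.
#' @return list: `phi` named numeric vector, `phi0` base value
#'   (`mean(predict_fn(background))`).
#' @export
brute_force_shapley <- function(predict_fn, x, background) {
  background <- as.matrix(background)
  d <- length(x)
  stop_if(d > 15, "brute force is capped at 15 features (2^d enumeration)")
  stop_if(nrow(background) < 1, "empty background")
  stop_if(ncol(background) != d, "background/instance width mismatch")
  B <- nrow(background)
  n_mask <- bitwShiftL(1L, d)
  # v(S) for every coalition mask
  v <- numeric(n_mask)
  for (mask in 0:(n_mask - 1L)) {
    comp <- background
    for (i in seq_len(d))
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) comp[, i] <- x[[i]]
    v[mask + 1L] <- mean(predict_fn(comp))
  }
  fact <- factorial(0:d)
  phi <- numeric(d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(n_mask - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(d) - 1L)) != 0L)
      w <- fact[s + 1L] * fact[d - s] / fact[d + 1L]
      phi[i] <- phi[i] + w * (v[mask + bit + 1L] - v[mask + 1L])
    }
  }
  names(phi) <- colnames(background)
  list(phi = phi, phi0 = v[1L])
}

#' Exact interventional Shapley attribution for one instance
#'
#' Equals [brute_force_shapley()] of the ensemble's margin function on the
#' same background, at polynomial cost (per tree: leaves x depth per
#' instance after a leaves x background precomputation).
#'
#' @param ensemble a `tree_ensemble`.
#' @param x named numeric vector (or one-row matrix) matching the model's
#'   features.
#' @param background numeric matrix of reference rows.
#' @return list: `phi` named numeric vector (margin units), `phi0` base
#'   value (expected margin over the background).
#' @export
tree_shapley <- function(ensemble, x, background) {
  am <- explain_cohort(ensemble,
                       if (is.null(dim(x)))
                         matrix(x, 1, dimnames = list(NULL, names(x)))
                       else x,
                       background)
  list(phi = setNames(am$phi[1, ], colnames(am$phi)), phi0 = am$phi0)
}

#' Shapley attributions for a whole cohort
#'
#' Runs the exact per-tree interventional engine over every row of `X` and
#' verifies local accuracy (phi0 + sum(phi) = margin) row by row.
#'
#' @param ensemble a `tree_ensemble`.
#' @param X feature matrix (episodes x features; rownames carry episode ids).
#' @param background numeric matrix of reference rows (see
#'   [sample_background()]).
#' @param check local-accuracy tolerance (default `1e-8`); `NULL` disables.
#' @return an `attribution_matrix`: list with `phi` (episodes x features
#'   matrix, margin units), `phi0` (scalar base value), `margin` (per-row
#'   model margin), `episode_id`.
#' @export
explain_cohort <- function(ensemble, X, background, check = 1e-8) {
  stop_if(nrow(X) == 0, "empty cohort")
  X <- .align_columns(ensemble, X)
  Z <- .align_columns(ensemble, background)
  fl <- .flatten_for_cpp(ensemble)
  phi <- cpp_tree_shapley(X, Z, fl$feature, fl$threshold, fl$yes, fl$no,
                          fl$missing, fl$value, fl$offset)
  colnames(phi) <- ensemble$feature_names
  margin <- predict_ensemble(ensemble, X, "margin")
  phi0 <- ensemble$base_score + mean(.ensemble_margin_raw(ensemble, Z))
  if (!is.null(check)) {
    resid <- abs(phi0 + rowSums(phi) - margin)
    bad <- which(resid > check)
    stop_if(length(bad) > 0,
            "local accuracy violated for rows: ",
            paste(head(rownames(X)[bad] %||% bad, 5), collapse = ", "))
  }
  structure(list(phi = phi, phi0 = phi0, margin = margin,
                 episode_id = rownames(X)),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat("<attribution_matrix>", nrow(x$phi), "episodes x", ncol(x$phi),
      "features; phi0 =", signif(x$phi0, 6), "(margin space)\n")
  invisible(x)
}

#' Rescale an attribution row from margin to probability units
#'
#' Display helper: distributes the sigmoid-scale change
#' `risk(x) - sigmoid(phi0)` over features proportionally to their margin
#' attributions. Margin-space values stay the exact quantity; downstream
#' normalised shares are identical in either space.
#'
#' @param attributions an `attribution_matrix`.
#' @return matrix of per-feature probability-scale contributions.
#' @export
attribution_probability_scale <- function(attributions) {
  total <- rowSums(attributions$phi)
  target <- sigmoid(attributions$margin) - sigmoid(attributions$phi0)
  scale <- ifelse(total == 0, 0, target / total)
  attributions$phi * scale
}

#' Write / read an attribution matrix as CSV
#'
#' Columns: `episode_id`, `phi0`, then one `phi` column per feature.
#'
#' @param attributions an `attribution_matrix`.
#' @param path file path.
#' @return `read_attributions` returns the `attribution_matrix`;
#'   `write_attributions` returns `path` invisibly.
#' @export
write_attributions <- function(attributions, path) {
  df <- data.frame(
    episode_id = attributions$episode_id %||%
      seq_len(nrow(attributions$phi)),
    phi0 = attributions$phi0,
    attributions$phi, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_attributions
#' @export
read_attributions <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  phi <- as.matrix(df[, setdiff(names(df), c("episode_id", "phi0")),
                      drop = FALSE])
  structure(list(phi = phi, phi0 = df$phi0[1],
                 margin = df$phi0[1] + rowSums(phi),
                 episode_id = as.character(df$episode_id)),
            class = "attribution_matrix")
}
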