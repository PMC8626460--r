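# Gradient-boosted tree classifier behind a thin adapter. The fitted backend
# (xgboost) is immediately distilled into a self-contained flat tree
# representation -- split feature, threshold, children, missing-default
# branch, leaf margins -- which is the unit every downstream computation
# (prediction, Shapley attribution, serialisation) operates on. Margins are
# log-odds; risk = sigmoid(margin).

.default_hyperparams <- function() {
  list(nrounds = 200L, max_depth = 4L, eta = 0.1, subsample = 0.8,
       colsample_bytree = 0.8, min_child_weight = 1)
}

#' Fit a gradient-boosted tree admission classifier
#'
#' Fits a binary logistic boosted-tree model and extracts it into the
#' package's internal `tree_ensemble` representation. Extraction is
#' faithful: internal margins reproduce backend margins to < 1e-6 (checked
#' on the training rows at fit time). Missing feature values are handled
#' natively via per-node default branches; nothing is imputed.
#'
#' @param X numeric feature matrix (`NA` = missing) with column names.
#' @param y binary 0/1 outcome vector.
#' @param hyperparams named list overriding the defaults
#'   (`nrounds = 200, max_depth = 4, eta = 0.1, subsample = 0.8,
#'   colsample_bytree = 0.8, min_child_weight = 1`).
#' @param seed integer seed (single-threaded fit, fully deterministic).
#' @return a `tree_ensemble`: list of flat per-tree node tables,
#'   `base_score` (margin offset) and `feature_names`.
#' @export
fit_tree_ensemble <- function(X, y, hyperparams = list(), seed = 1L) {
  stop_if(anyNA(y), "missing labels")
  stop_if(length(unique(y)) < 2, "labels are single-class; cannot fit")
  hp <- modifyList(.default_hyperparams(), hyperparams)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, missing = NA)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", base_score = 0.5,
                  max_depth = hp$max_depth, eta = hp$eta,
                  subsample = hp$subsample,
                  colsample_bytree = hp$colsample_bytree,
                  min_child_weight = hp$min_child_weight,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = hp$nrounds, verbose = 0))
  ens <- .extract_ensemble(booster, colnames(X))
  # fidelity: align base_score so internal margins match the backend.
  # the round-trip comparison replicates the backend's single-precision
  # accumulation; routine prediction accumulates in double.
  backend <- predict(booster, xgboost::xgb.DMatrix(as.matrix(X), missing = NA),
                     outputmargin = TRUE)
  raw <- .ensemble_margin_raw(ens, as.matrix(X), float_acc = TRUE)
  offs <- backend - raw
  stop_if(diff(range(offs)) > 1e-5,
          "tree extraction unfaithful: margin residuals are not constant")
  ens$base_score <- mean(offs)
  stop_if(max(abs(offs - ens$base_score)) > 1e-6, "tree extraction unfaithful")
  ens
}

# Parse the backend's JSON dump into flat per-tree node tables.
.extract_ensemble <- function(booster, feature_names) {
  dump <- xgboost::xgb.dump(booster, dump_format = "json", with_stats = FALSE)
  trees_json <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
                                   simplifyVector = FALSE)
  trees <- lapply(trees_json, .flatten_tree, feature_names = feature_names)
  structure(list(trees = trees, base_score = 0,
                 feature_names = feature_names),
            class = "tree_ensemble")
}

# One tree -> data.frame(feature, threshold, yes, no, missing, value) with
# 0-based node ids in row order; feature = -1 marks a leaf. `yes` is the
# x < threshold branch, mirroring the backend's split semantics.
.flatten_tree <- function(node, feature_names) {
  rows <- list()
  walk <- function(nd) {
    id <- nd$nodeid
    if (!is.null(nd$leaf)) {
      rows[[as.character(id)]] <<- c(feature = -1L, threshold = 0,
                                     yes = -1L, no = -1L, missing = -1L,
                                     value = nd$leaf)
      return(invisible())
    }
    fx <- nd$split
    fi <- if (grepl("^f[0-9]+$", fx) && !fx %in% feature_names)
      as.integer(sub("^f", "", fx)) else match(fx, feature_names) - 1L
    stop_if(is.na(fi), "unknown split feature in dump: ", fx)
    rows[[as.character(id)]] <<- c(feature = fi, threshold = nd$split_condition,
                                   yes = nd$yes, no = nd$no,
                                   missing = nd$missing, value = 0)
    for (ch in nd$children) walk(ch)
  }
  walk(node)
  ids <- sort(as.integer(names(rows)))
  tab <- do.call(rbind, rows[as.character(ids)])
  # re-index node ids to consecutive row positions (0-based)
  pos <- setNames(seq_along(ids) - 1L, ids)
  out <- as.data.frame(tab)
  for (cc in c("yes", "no", "missing"))
    out[[cc]] <- ifelse(out[[cc]] < 0, -1L, unname(pos[as.character(out[[cc]])]))
  out$feature <- as.integer(out$feature)
  rownames(out) <- NULL
  out
}

# Flatten an ensemble into the parallel arrays the C++ kernels consume.
.flatten_for_cpp <- function(ens) {
  tr <- ens$trees
  sizes <- vapply(tr, nrow, integer(1))
  list(
    feature = unlist(lapply(tr, `[[`, "feature")),
    threshold = unlist(lapply(tr, `[[`, "threshold")),
    yes = unlist(lapply(tr, `[[`, "yes")),
    no = unlist(lapply(tr, `[[`, "no")),
    missing = unlist(lapply(tr, `[[`, "missing")),
    value = unlist(lapply(tr, `[[`, "value")),
    offset = c(0L, cumsum(sizes))
  )
}

.ensemble_margin_raw <- function(ens, X, float_acc = FALSE) {
  fl <- .flatten_for_cpp(ens)
  cpp_predict_margin(X, fl$feature, fl$threshold, fl$yes, fl$no, fl$missing,
                     fl$value, fl$offset, float_acc)
}

#' Predict margins or admission risks from a tree ensemble
#'
#' Traverses the internal representation: at each split, a missing feature
#' value routes down the node's default branch; otherwise `x < threshold`
#' goes to the `yes` child. The margin is `base_score` plus the sum of leaf
#' values over trees; risk applies the logistic link.
#'
#' @param ensemble a `tree_ensemble`.
#' @param X numeric matrix with columns matching `feature_names` (a named
#'   vector is treated as one row).
#' @param output `"margin"` (log-odds) or `"risk"` (probability).
#' @return numeric vector, one value per row.
#' @export
predict_ensemble <- function(ensemble, X, output = c("risk", "margin")) {
  output <- match.arg(output)
  X <- .align_columns(ensemble, X)
  m <- ensemble$base_score + .ensemble_margin_raw(ensemble, X)
  if (output == "risk") sigmoid(m) else m
}

.align_columns <- function(ensemble, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(ensemble$feature_names)) {
    stop_if(!all(ensemble$feature_names %in% colnames(X)),
            "feature matrix is missing model columns: ",
            paste(setdiff(ensemble$feature_names, colnames(X)), collapse = ", "))
    X <- X[, ensemble$feature_names, drop = FALSE]
  } else {
    stop_if(ncol(X) != length(ensemble$feature_names),
            "column count does not match the model's feature set")
  }
  storage.mode(X) <- "double"
  X
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("<tree_ensemble>", length(x$trees), "trees over",
      length(x$feature_names), "features; base_score =",
      signif(x$base_score, 6), "\n")
  invisible(x)
}

#' Serialise / load a tree ensemble as JSON
#'
#' Trees are stored as flat node tables; the loader re-validates structural
#' invariants (both children present on internal nodes, missing-default
#' pointing at a child, every node reachable exactly once).
#'
#' @param ensemble a `tree_ensemble`.
#' @param path file path.
#' @return `read_ensemble` returns the ensemble; `write_ensemble` returns
#'   `path` invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  doc <- list(base_score = ensemble$base_score,
              feature_names = as.list(ensemble$feature_names),
              trees = lapply(ensemble$trees, as.list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  trees <- lapply(doc$trees, function(tr) data.frame(
    feature = as.integer(unlist(tr$feature)),
    threshold = as.numeric(unlist(tr$threshold)),
    yes = as.integer(unlist(tr$yes)),
    no = as.integer(unlist(tr$no)),
    missing = as.integer(unlist(tr$missing)),
    value = as.numeric(unlist(tr$value))))
  ens <- structure(list(trees = trees, base_score = doc$base_score,
                        feature_names = as.character(unlist(doc$feature_names))),
                   class = "tree_ensemble")
  for (tr in ens$trees) .validate_tree(tr, length(ens$feature_names))
  ens
}

.validate_tree <- function(tr, n_feat) {
  internal <- tr$feature >= 0
  stop_if(any(tr$feature[internal] >= n_feat), "split feature out of range")
  stop_if(any(tr$yes[internal] < 0 | tr$no[internal] < 0),
          "internal node lacking a child")
  stop_if(any(tr$missing[internal] != tr$yes[internal] &
              tr$missing[internal] != tr$no[internal]),
          "missing-default branch must point at a child")
  # reachability: every node except the root is a child exactly once
  kids <- c(tr$yes[internal], tr$no[internal])
  stop_if(any(sort(kids) != setdiff(seq_len(nrow(tr)) - 1L, 0L)),
          "tree nodes are not a single binary tree")
  invisible(tr)
}

#' Small k-fold grid search over boosting hyperparameters
#'
#' Desk-scale stand-in for a full hyperparameter search: evaluates each
#' candidate by k-fold cross-validated AUROC and returns the best set.
#'
#' @param X,y as in [fit_tree_ensemble()].
#' @param grid data.frame of candidate hyperparameter rows (columns among
#'   the hyperparameter names).
#' @param k folds (default 5).
#' @param seed integer seed for fold assignment and fits.
#' @return list: `best` hyperparameter list, `results` data.frame with mean
#'   CV AUROC per candidate.
#' @export
tune_tree_ensemble <- function(X, y, grid, k = 5, seed = 1L) {
  folds <- with_seed(seed, sample(rep_len(seq_len(k), length(y))))
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      ens <- fit_tree_ensemble(X[tr, , drop = FALSE], y[tr], hp, seed = seed)
      auroc(predict_ensemble(ens, X[!tr, , drop = FALSE], "margin"), y[!tr])
    }, numeric(1))
    score[g] <- mean(aucs)
  }
  best <- as.list(grid[which.max(score), , drop = FALSE])
  list(best = best, results = cbind(grid, cv_auroc = score))
}
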