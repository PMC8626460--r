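# Shared fixtures, built in code. Expensive objects are computed lazily and
# cached for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# hand-built single tree: x1 < 0.5 -> leaf -1, else leaf +1; missing right
make_stump <- function(feature = 0L, thr = 0.5, left = -1, right = 1,
                       missing = "right", feature_names = c("x1", "x2")) {
  tree <- data.frame(
    feature = c(feature, -1L, -1L),
    threshold = c(thr, 0, 0),
    yes = c(1L, -1L, -1L),
    no = c(2L, -1L, -1L),
    missing = c(if (missing == "right") 2L else 1L, -1L, -1L),
    value = c(0, left, right))
  structure(list(trees = list(tree), base_score = 0,
                 feature_names = feature_names),
            class = "tree_ensemble")
}

# AND-tree: leaf 1 iff x1 > 0.5 and x2 > 0.5, else 0
make_and_tree <- function() {
  tree <- data.frame(
    feature = c(0L, -1L, 1L, -1L, -1L),
    threshold = c(0.5, 0, 0.5, 0, 0),
    yes = c(1L, -1L, 3L, -1L, -1L),
    no = c(2L, -1L, 4L, -1L, -1L),
    missing = c(1L, -1L, 3L, -1L, -1L),
    value = c(0, 0, 0, 0, 1))
  structure(list(trees = list(tree), base_score = 0,
                 feature_names = c("x1", "x2")),
            class = "tree_ensemble")
}

# a small fitted pipeline reused across test files
small_pipeline <- function() {
  fixture("small_pipeline", function() {
    sc <- make_scenario("baseline", horizon_weeks = 6, weekly_volume = 200)
    ep <- simulate_cohort(sc, seed = 42)
    enc <- encode_table(ep, "fit")
    ens <- fit_tree_ensemble(enc$X, ep$outcome, list(nrounds = 40), seed = 1)
    bg <- sample_background(enc$X, 64, seed = 2)
    list(sc = sc, ep = ep, enc = enc, ens = ens, bg = bg)
  })
}

# random fitted ensemble with missing-valued data, for oracle sweeps
random_ensemble_case <- function(seed, d = NULL, n_trees = NULL,
                                 depth = NULL, n_background = 6) {
  set.seed(seed)
  d <- d %||% sample(3:10, 1)
  n_trees <- n_trees %||% sample(5:50, 1)
  depth <- depth %||% sample(2:4, 1)
  n <- 300
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
  X[sample(length(X), round(0.15 * length(X)))] <- NA
  lin <- rowSums(X[, 1:min(3, d), drop = FALSE], na.rm = TRUE)
  y <- rbinom(n, 1, plogis(lin))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  ens <- fit_tree_ensemble(X, y, list(nrounds = n_trees, max_depth = depth),
                           seed = seed)
  x <- X[sample(n, 1), ]
  bg <- X[sample(n, n_background), , drop = FALSE]
  list(ens = ens, x = x, bg = bg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
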