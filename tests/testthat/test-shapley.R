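# Shapley attribution: brute-force coalition oracle, exact tree engine,
# their equivalence, and the Shapley axioms.

test_that("brute force solves the single-player game exactly", {
  f <- function(M) 3 * M[, 1]
  bg <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "x1"))
  out <- brute_force_shapley(f, c(x1 = 5), bg)
  expect_equal(unname(out$phi), 15 - 3)
  expect_equal(out$phi0, 3)
})

test_that("brute force reproduces the AND-game by-hand enumeration", {
  ens <- make_and_tree()
  corners <- as.matrix(expand.grid(x1 = c(0, 1), x2 = c(0, 1)))
  out <- brute_force_shapley(function(M) predict_ensemble(ens, M, "margin"),
                             c(x1 = 1, x2 = 1), corners)
  # v(empty)=1/4, v({1})=v({2})=1/2, v({1,2})=1
  expect_equal(out$phi0, 0.25)
  expect_equal(unname(out$phi), c(0.375, 0.375))
})

test_that("the exact tree engine matches the AND-game values", {
  ens <- make_and_tree()
  corners <- as.matrix(expand.grid(x1 = c(0, 1), x2 = c(0, 1)))
  out <- tree_shapley(ens, c(x1 = 1, x2 = 1), corners)
  expect_equal(out$phi0, 0.25, tolerance = 1e-12)
  expect_equal(unname(out$phi), c(0.375, 0.375), tolerance = 1e-12)
})

test_that("symmetric features with equal values get equal attributions", {
  # two stumps with identical structure on different features
  s1 <- make_stump(feature = 0L, thr = 0, left = 0, right = 1)
  s2 <- make_stump(feature = 1L, thr = 0, left = 0, right = 1)
  ens <- s1
  ens$trees <- c(s1$trees, s2$trees)
  bg <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("x1", "x2")))
  bg[, 2] <- bg[, 1]  # symmetric background too
  out <- tree_shapley(ens, c(x1 = 0.7, x2 = 0.7), bg)
  expect_equal(out$phi[["x1"]], out$phi[["x2"]], tolerance = 1e-12)
})

test_that("features unused by any tree receive exactly zero", {
  st <- make_stump()  # splits only on x1
  bg <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("x1", "x2")))
  out <- tree_shapley(st, c(x1 = 2, x2 = 99), bg)
  expect_identical(out$phi[["x2"]], 0)
})

test_that("attributions of additive trees follow the per-feature closed form", {
  s1 <- make_stump(feature = 0L, thr = 0.5, left = -1, right = 1)
  s2 <- make_stump(feature = 1L, thr = -0.2, left = 2, right = -3)
  ens <- s1
  ens$trees <- c(s1$trees, s2$trees)
  set.seed(4)
  bg <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  x <- c(x1 = 0.9, x2 = -1)
  f1 <- function(v) ifelse(v < 0.5, -1, 1)
  f2 <- function(v) ifelse(v < -0.2, 2, -3)
  out <- tree_shapley(ens, x, bg)
  expect_equal(out$phi[["x1"]], unname(f1(x[1]) - mean(f1(bg[, 1]))),
               tolerance = 1e-12)
  expect_equal(out$phi[["x2"]], unname(f2(x[2]) - mean(f2(bg[, 2]))),
               tolerance = 1e-12)
})

test_that("tree engine equals the brute-force oracle on random fitted models", {
  for (s in 1:8) {
    case <- random_ensemble_case(700 + s, d = sample(3:8, 1))
    bf <- brute_force_shapley(
      function(M) predict_ensemble(case$ens, M, "margin"), case$x, case$bg)
    tr <- tree_shapley(case$ens, case$x, case$bg)
    expect_lt(max(abs(bf$phi - tr$phi)), 1e-8)
    expect_lt(abs(bf$phi0 - tr$phi0), 1e-8)
  }
})

test_that("oracle equivalence holds when the instance itself has missing values", {
  case <- random_ensemble_case(77, d = 5)
  case$x[c(1, 3)] <- NA
  bf <- brute_force_shapley(
    function(M) predict_ensemble(case$ens, M, "margin"), case$x, case$bg)
  tr <- tree_shapley(case$ens, case$x, case$bg)
  expect_lt(max(abs(bf$phi - tr$phi)), 1e-8)
})

test_that("attributions are additive across trees", {
  case <- random_ensemble_case(55, d = 4, n_trees = 6)
  full <- tree_shapley(case$ens, case$x, case$bg)
  parts <- lapply(seq_along(case$ens$trees), function(i) {
    one <- case$ens
    one$trees <- case$ens$trees[i]
    one$base_score <- 0
    tree_shapley(one, case$x, case$bg)$phi
  })
  expect_equal(full$phi, Reduce(`+`, parts), tolerance = 1e-10)
})

test_that("explain_cohort preserves rows, determinism and local accuracy", {
  fx <- small_pipeline()
  X <- fx$enc$X[1:30, ]
  am <- explain_cohort(fx$ens, X, fx$bg)
  expect_equal(nrow(am$phi), 30)
  expect_equal(am$episode_id, rownames(X))
  expect_lt(max(abs(am$phi0 + rowSums(am$phi) - am$margin)), 1e-8)
  # single row equals tree_shapley
  one <- tree_shapley(fx$ens, X[1, ], fx$bg)
  expect_equal(unname(am$phi[1, ]), unname(one$phi), tolerance = 1e-12)
  # duplicated rows explain identically
  X2 <- X[c(1, 1), ]
  am2 <- explain_cohort(fx$ens, X2, fx$bg)
  expect_identical(am2$phi[1, ], am2$phi[2, ])
  expect_error(explain_cohort(fx$ens, X[0, , drop = FALSE], fx$bg), "empty")
})

test_that("probability-scale view redistributes the sigmoid gap over features", {
  fx <- small_pipeline()
  am <- explain_cohort(fx$ens, fx$enc$X[1:20, ], fx$bg)
  pr <- attribution_probability_scale(am)
  expect_equal(rowSums(pr), plogis(am$margin) - plogis(am$phi0),
               tolerance = 1e-10)
})

test_that("attribution CSV round trip preserves phi and base value", {
  fx <- small_pipeline()
  am <- explain_cohort(fx$ens, fx$enc$X[1:10, ], fx$bg)
  path <- tempfile(fileext = ".csv")
  write_attributions(am, path)
  back <- read_attributions(path)
  expect_equal(back$phi, am$phi, tolerance = 1e-10,
               ignore_attr = "dimnames")
  expect_equal(back$phi0, am$phi0, tolerance = 1e-12)
  expect_equal(back$episode_id, am$episode_id)
})

test_that("guards reject oversized or mismatched problems", {
  f <- function(M) rowSums(M)
  expect_error(brute_force_shapley(f, rep(0, 16),
                                   matrix(0, 1, 16)), "capped")
  expect_error(brute_force_shapley(f, c(a = 1),
                                   matrix(0, 0, 1)), "empty background")
})
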