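# Synthetic ED stream generator: scenario construction, the logistic ground
# truth, drift-event semantics and reproducibility.

zeroed_specs <- function(sc) {
  # null mechanism: every coefficient zero
  sc$numeric_specs <- lapply(sc$numeric_specs, function(s) {
    s$beta <- 0; s
  })
  sc$categorical_specs <- lapply(sc$categorical_specs, function(s) {
    s$coefs[] <- 0; s
  })
  sc$history_specs <- lapply(sc$history_specs, function(s) {
    s$beta <- 0; s
  })
  sc
}

test_that("scenario construction validates kinds, onsets and probabilities", {
  expect_error(make_scenario("unknown_family"), "unknown scenario kind")
  expect_error(make_scenario("covariate_shift", t_star = 60,
                             horizon_weeks = 52), "outside horizon")
  sc <- make_scenario("baseline")
  expect_length(sc$drift_events, 0)
  for (s in sc$categorical_specs)
    expect_equal(sum(s$probs), 1, tolerance = 1e-12)
  sc2 <- make_scenario("prevalence_shift", delta = 1.0, t_star = 40)
  expect_equal(sc2$drift_events[[1]]$delta, 1.0)
  expect_equal(scenario_params_at(sc2, 39)$delta0, 0)
  expect_equal(scenario_params_at(sc2, 40)$delta0, 1.0)
})

test_that("category emergence adds a level and keeps masses normalised", {
  sc <- make_scenario("category_emergence", mass = 0.2, t_star = 10,
                      horizon_weeks = 20)
  pre <- scenario_params_at(sc, 9)$categorical$attendance_complaint$probs
  post <- scenario_params_at(sc, 10)$categorical$attendance_complaint$probs
  expect_false("covid19" %in% names(pre))
  expect_equal(unname(post["covid19"]), 0.2)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  # mass taken proportionally from existing levels
  expect_equal(unname(post[names(pre)] / pre), rep(0.8, length(pre)),
               tolerance = 1e-12)
})

test_that("null mechanism reproduces the configured admission rate", {
  sc <- zeroed_specs(make_scenario("baseline", horizon_weeks = 10,
                                   weekly_volume = 1000,
                                   base_admission_rate = 0.3))
  ep <- simulate_cohort(sc, n = 10000, seed = 5)
  ci <- stats::binom.test(sum(ep$outcome), nrow(ep), 0.3,
                          conf.level = 0.99)$p.value
  expect_gt(ci, 0.01)
  # with all coefficients zero the intercept is exactly logit(rate)
  expect_equal(shapdrift:::scenario_intercept(sc), stats::qlogis(0.3),
               tolerance = 1e-9)
})

test_that("calibrated intercept hits the target marginal rate", {
  sc <- make_scenario("baseline", horizon_weeks = 10, weekly_volume = 2000)
  ep <- simulate_cohort(sc, seed = 3)
  expect_lt(abs(mean(ep$outcome) - 0.30), 0.015)
})

test_that("simulation is deterministic and degenerate inputs are handled", {
  sc <- make_scenario("baseline", horizon_weeks = 4, weekly_volume = 50)
  a <- simulate_cohort(sc, seed = 9)
  b <- simulate_cohort(sc, seed = 9)
  expect_identical(a, b)
  e <- simulate_cohort(sc, n = 0, seed = 9)
  expect_equal(nrow(e), 0)
  expect_true(all(c("episode_id", "timestamp", "outcome", "age",
                    "arrival_mode") %in% names(e)))
})

test_that("episode ids are unique and timestamps stay within the horizon", {
  sc <- make_scenario("baseline", horizon_weeks = 5, weekly_volume = 120)
  ep <- simulate_cohort(sc, seed = 2)
  expect_false(any(duplicated(ep$episode_id)))
  expect_true(all(ep$timestamp >= as.POSIXct(sc$start_date, tz = "UTC")))
  expect_true(all(ep$timestamp <
                  as.POSIXct(sc$start_date, tz = "UTC") + 5 * 7 * 86400))
  expect_true(all(ep$outcome %in% c(0L, 1L)))
})

test_that("true_risk matches the closed-form mechanism", {
  sc <- zeroed_specs(make_scenario("baseline", base_admission_rate = 0.3))
  rec <- simulate_cohort(sc, n = 1, seed = 1)
  expect_equal(true_risk(rec, sc, 0), 0.3, tolerance = 1e-9)

  # single live coefficient: beta = 0.5 on resp_rate, x two sd above mean
  sc2 <- zeroed_specs(make_scenario("baseline", base_admission_rate = 0.5))
  sc2$numeric_specs$resp_rate$beta <- 0.5
  rec$resp_rate <- sc2$numeric_specs$resp_rate$mean +
    2 * sc2$numeric_specs$resp_rate$sd
  expect_equal(true_risk(rec, sc2, 0), plogis(1.0), tolerance = 1e-6)

  # monotone in a positive-coefficient feature
  risks <- vapply(seq(10, 40, by = 2), function(v) {
    rec$resp_rate <- v
    true_risk(rec, sc2, 0)
  }, numeric(1))
  expect_true(all(diff(risks) >= 0))

  # unknown level outside the emergence window errors
  sc3 <- make_scenario("baseline")
  rec$attendance_complaint <- "covid19"
  expect_error(true_risk(rec, sc3, 0), "unknown level")
})

test_that("baseline streams are stationary week to week", {
  sc <- make_scenario("baseline", horizon_weeks = 8, weekly_volume = 600)
  ep <- simulate_cohort(sc, seed = 21)
  for (w in unique(ep$week)) {
    sub <- ep[ep$week == w, ]
    # weekly admission rate within exact binomial 99.9% bounds of the pooled rate
    p <- stats::binom.test(sum(sub$outcome), nrow(sub),
                           mean(ep$outcome))$p.value
    expect_gt(p, 0.001)
    p2 <- stats::binom.test(sum(sub$arrival_mode == "walk_in"), nrow(sub),
                            mean(ep$arrival_mode == "walk_in"))$p.value
    expect_gt(p2, 0.001)
    p3 <- stats::binom.test(sum(is.na(sub$resp_rate)), nrow(sub),
                            mean(is.na(ep$resp_rate)))$p.value
    expect_gt(p3, 0.001)
  }
})

test_that("prevalence shift moves the outcome scale but not the covariates", {
  n <- 5000
  base <- make_scenario("baseline", horizon_weeks = 2, weekly_volume = n)
  shift <- make_scenario("prevalence_shift", horizon_weeks = 2,
                         weekly_volume = n, t_star = 1)
  ks_p <- numeric(0)
  rate_gap <- numeric(0)
  for (s in 1:20) {
    ep <- simulate_cohort(shift, seed = 500 + s)
    pre <- ep[ep$week == 0, ]; post <- ep[ep$week == 1, ]
    rate_gap <- c(rate_gap, mean(post$outcome) - mean(pre$outcome))
    ks_p <- c(ks_p, suppressWarnings(
      stats::ks.test(pre$age, post$age)$p.value))
  }
  expect_true(all(rate_gap > 0.1))
  # marginals indistinguishable: Bonferroni-adjusted KS across 20 seeds
  expect_true(all(stats::p.adjust(ks_p, "bonferroni") > 0.01))
})

test_that("concept shift flips the feature-outcome association, not the marginal", {
  n <- 20000
  sc <- make_scenario("concept_shift", horizon_weeks = 2, weekly_volume = n,
                      t_star = 1)
  ep <- simulate_cohort(sc, seed = 31)
  pre <- ep[ep$week == 0, ]; post <- ep[ep$week == 1, ]
  hi <- function(d) d$resp_rate > 22 & !is.na(d$resp_rate)
  lo <- function(d) d$resp_rate <= 22 & !is.na(d$resp_rate)
  # pre: high respiration rate raises admission; post: lowers it
  expect_gt(mean(pre$outcome[hi(pre)]), mean(pre$outcome[lo(pre)]))
  expect_lt(mean(post$outcome[hi(post)]), mean(post$outcome[lo(post)]))
  expect_lt(mean(post$outcome[hi(post)]), mean(pre$outcome[hi(pre)]))
  # the respiration-rate marginal itself is unchanged
  expect_gt(suppressWarnings(
    stats::ks.test(pre$resp_rate, post$resp_rate)$p.value), 0.01)
})

test_that("episode CSV round trip preserves the table and its missingness", {
  sc <- make_scenario("baseline", horizon_weeks = 3, weekly_volume = 80)
  ep <- simulate_cohort(sc, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_episodes(ep, path)
  header <- readLines(path, n = 1)
  expect_match(header, "^episode_id,timestamp,outcome,age,")
  back <- read_episodes(path)
  expect_equal(back$episode_id, ep$episode_id)
  expect_equal(is.na(back$resp_rate), is.na(ep$resp_rate))
  expect_equal(back$resp_rate, ep$resp_rate, tolerance = 1e-6)
  expect_equal(as.numeric(back$timestamp), as.numeric(ep$timestamp),
               tolerance = 1)
  expect_equal(back$outcome, ep$outcome)
})
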