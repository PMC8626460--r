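# Flagging rules, the drift-type rule table, and end-to-end reproducibility.

mk_series <- function(means, n = 200, feature = "f1", start_week = 0) {
  data.frame(feature = feature, week = start_week + seq_along(means) - 1,
             week_start = as.Date("2019-04-01") + 7 * (seq_along(means) - 1),
             mean = means, ci_lo = means - 0.01, ci_hi = means + 0.01, n = n)
}

test_that("importance flagging needs persistent excursions", {
  set.seed(1)
  base <- matrix(runif(4000, 0.4, 0.6), ncol = 2,
                 dimnames = list(NULL, c("f1", "f2")))
  base <- base / rowSums(base)
  # single-bin excursion with k_consec = 2 is never flagged
  ser1 <- mk_series(c(0.5, 0.9, 0.5, 0.5))
  f1 <- flag_importance_drift(ser1, base, k_consec = 2, n_boot = 300,
                              seed = 1)
  expect_equal(nrow(f1), 0)
  # sustained excursion flags from its second bin onwards
  ser2 <- mk_series(c(0.5, 0.9, 0.9, 0.9))
  f2 <- flag_importance_drift(ser2, base, k_consec = 2, n_boot = 300,
                              seed = 1)
  expect_equal(f2$week, c(2, 3))
  expect_true(all(f2$direction == "up"))
  # an on-baseline series is quiet
  ser3 <- mk_series(rep(0.5, 6))
  expect_equal(nrow(flag_importance_drift(ser3, base, n_boot = 300,
                                          seed = 1)), 0)
  # direction reversals reset the run
  ser4 <- mk_series(c(0.9, 0.1, 0.9, 0.1))
  expect_equal(nrow(flag_importance_drift(ser4, base, k_consec = 2,
                                          n_boot = 300, seed = 1)), 0)
})

test_that("performance flagging requires consecutive CIs below reference", {
  ser <- data.frame(week = 0:5, auroc = c(0.84, 0.80, 0.79, 0.85, 0.78, 0.77),
                    ci_lo = NA, ci_hi = c(0.87, 0.82, 0.81, 0.88, 0.80, 0.79),
                    n = 100)
  fl <- flag_performance_drift(ser, reference_auroc = 0.85, k_consec = 2)
  expect_equal(fl$week, c(2, 5))  # second bin of each run of two
  # overlapping CIs never flag
  ser$ci_hi <- 0.9
  expect_equal(nrow(flag_performance_drift(ser, 0.85)), 0)
  # undefined bins are skipped: the run continues across them
  ser2 <- data.frame(week = 0:2, auroc = c(0.7, NA, 0.7),
                     ci_lo = NA, ci_hi = c(0.72, NA, 0.72), n = 10)
  fl2 <- flag_performance_drift(ser2, 0.85, k_consec = 2)
  expect_equal(fl2$week, 2)
})

test_that("the drift-type rule table is exhaustive and window-aware", {
  imp <- data.frame(feature = "f1", week = 5, direction = "up",
                    mean = 0.3, null_lo = 0.1, null_hi = 0.2)
  perf <- data.frame(week = 6, auroc = 0.7, ci_hi = 0.75, pooled = FALSE)
  none <- imp[0, ]
  perf_none <- perf[0, ]
  expect_equal(classify_drift(imp, perf_none), "data_drift_no_degradation")
  expect_equal(classify_drift(none, perf), "concept_drift_suspected")
  expect_equal(classify_drift(imp, perf), "data_drift_with_degradation")
  expect_equal(classify_drift(none, perf_none), "stable")
  # flags outside the window are ignored
  expect_equal(classify_drift(imp, perf, window = c(10, 12)), "stable")
  # pure function: repeated application gives the same answer
  expect_equal(classify_drift(imp, perf), classify_drift(imp, perf))
})

test_that("the full pipeline is reproducible for a fixed config and seed", {
  sc <- make_scenario("baseline", horizon_weeks = 9, weekly_volume = 150)
  cfg <- list(scenario = sc, train_weeks = 3, pre_weeks = 3,
              hyperparams = list(nrounds = 30), n_boot = 100,
              background_size = 64)
  r1 <- run_monitoring(cfg, seed = 5)
  r2 <- run_monitoring(cfg, seed = 5)
  expect_identical(r1$classification, r2$classification)
  expect_identical(r1$importance_series, r2$importance_series)
  expect_identical(r1$performance_series, r2$performance_series)
  expect_identical(r1$importance_flags, r2$importance_flags)
  expect_identical(r1$summary_pre, r2$summary_pre)
})

test_that("reports persist as JSON plus tidy CSVs", {
  sc <- make_scenario("baseline", horizon_weeks = 9, weekly_volume = 150)
  dir <- tempfile()
  rep <- run_monitoring(list(scenario = sc, train_weeks = 3, pre_weeks = 3,
                             hyperparams = list(nrounds = 30), n_boot = 100,
                             background_size = 64, out_dir = dir), seed = 5)
  expect_true(file.exists(file.path(dir, "drift_report.json")))
  doc <- jsonlite::read_json(file.path(dir, "drift_report.json"))
  expect_equal(doc$classification, rep$classification)
  ser <- read.csv(file.path(dir, "importance_series.csv"))
  expect_equal(nrow(ser), nrow(rep$importance_series))
  expect_true(file.exists(file.path(dir, "prevalence_arrival_mode.csv")))
})

test_that("monitoring an episode CSV gives the same report as the table", {
  sc <- make_scenario("baseline", horizon_weeks = 9, weekly_volume = 150)
  ep <- simulate_cohort(sc, seed = 6)
  path <- tempfile(fileext = ".csv")
  write_episodes(ep, path)
  cfg <- list(train_weeks = 3, pre_weeks = 3,
              hyperparams = list(nrounds = 30), n_boot = 100,
              background_size = 64)
  r_tab <- run_monitoring(c(list(episodes = ep), cfg), seed = 7)
  r_csv <- run_monitoring(c(list(episodes = path), cfg), seed = 7)
  expect_equal(r_csv$classification, r_tab$classification)
  expect_equal(r_csv$summary_pre$auroc$point, r_tab$summary_pre$auroc$point,
               tolerance = 1e-6)
})
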