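# Synthetic emergency-department attendance streams with a known logistic
# admission mechanism and injectable drift events. The generator emulates the
# phenomenology of a pre-pandemic ED feed hit by an abrupt operational shock:
# a walk-in collapse, an admission-rate jump, a rise in vital-sign recording,
# and an emergent complaint category unseen at training time.

# Default feature universe ---------------------------------------------------

.numeric_defaults <- function() {
  list(
    age         = list(mean = 55,   sd = 20,  beta =  0.6),
    resp_rate   = list(mean = 18,   sd = 4,   beta =  0.8),
    pulse_rate  = list(mean = 85,   sd = 18,  beta =  0.4),
    temperature = list(mean = 36.9, sd = 0.7, beta =  0.3),
    spo2        = list(mean = 96.5, sd = 2.5, beta = -0.6),
    news2       = list(mean = 2.5,  sd = 2,   beta =  0.7)
  )
}

# Vitals are recorded (or not) as a block at triage; age is always present.
.vital_names <- c("resp_rate", "pulse_rate", "temperature", "spo2", "news2")

.categorical_defaults <- function() {
  list(
    arrival_mode = list(
      probs = c(walk_in = 0.60, ambulance = 0.35, other = 0.05),
      coefs = c(walk_in = -0.4, ambulance = 0.9, other = 0)
    ),
    attendance_complaint = list(
      probs = c(chest_pain = 0.12, breathing_difficulty = 0.10,
                abdominal_pain = 0.12, injury = 0.20, wound = 0.12,
                unwell_adult = 0.14, limb_problem = 0.12, other = 0.08),
      coefs = c(chest_pain = 0.6, breathing_difficulty = 0.9,
                abdominal_pain = 0.3, injury = -0.5, wound = -0.8,
                unwell_adult = 0.2, limb_problem = -0.6, other = 0)
    ),
    triage_complaint = list(
      probs = c(pain = 0.25, breathing = 0.12, injury = 0.25,
                general_unwell = 0.20, minor = 0.18),
      coefs = c(pain = 0, breathing = 0.7, injury = -0.4,
                general_unwell = 0.3, minor = -0.6)
    ),
    triage_discriminator = list(
      probs = c(low_spo2 = 0.06, pleuritic_pain = 0.08,
                airway_compromise = 0.03, recent_problem = 0.30,
                recent_mild_pain = 0.25, moderate_pain = 0.18, other = 0.10),
      coefs = c(low_spo2 = 1.2, pleuritic_pain = 0.6, airway_compromise = 1.5,
                recent_problem = -0.5, recent_mild_pain = -0.7,
                moderate_pain = 0, other = 0.2)
    )
  )
}

.history_defaults <- function() {
  list(
    hx_hypertension = list(p = 0.25, beta = 0.3),
    hx_diabetes_t2  = list(p = 0.12, beta = 0.3),
    hx_copd         = list(p = 0.08, beta = 0.5),
    hx_asthma       = list(p = 0.10, beta = 0.2),
    hx_ihd          = list(p = 0.08, beta = 0.5),
    hx_ckd          = list(p = 0.06, beta = 0.4),
    hx_alcohol      = list(p = 0.07, beta = 0.3),
    hx_smoker       = list(p = 0.20, beta = 0.2)
  )
}

.scenario_kinds <- c("baseline", "covariate_shift", "prevalence_shift",
                     "missingness_shift", "category_emergence",
                     "concept_shift", "covid_like")

.drift_kinds <- c("covariate_shift", "prevalence_shift", "missingness_shift",
                  "category_emergence", "concept_shift")

# Scenario construction ------------------------------------------------------

#' Build a simulation scenario for a synthetic ED attendance stream
#'
#' A scenario fixes the covariate law \eqn{P_t(x)} and the outcome law
#' \eqn{P_t(y|x)} of an attendance stream over a weekly grid, plus a list of
#' step-change drift events at onset week `t_star`. The admission mechanism
#' is logistic: the true admission log-odds of an attendance are the
#' intercept plus per-standard-deviation coefficients on recorded numerics
#' (missing vitals contribute zero, i.e. the population mean), per-level
#' coefficients on categoricals, and per-flag coefficients on condition
#' history. The intercept is derived so the marginal admission rate matches
#' `base_admission_rate` at baseline.
#'
#' Scenario families:
#' \describe{
#'   \item{baseline}{time-constant parameters, no drift events.}
#'   \item{covariate_shift}{arrival-mode walk-in fraction steps
#'     `walkin_from` (0.6) to `walkin_to` (0.2) at `t_star`; outcome law
#'     unchanged.}
#'   \item{prevalence_shift}{intercept steps up by `delta` log-odds at
#'     `t_star` (default: the step that moves the marginal admission rate to
#'     `rate_to`, 0.5); covariate law unchanged.}
#'   \item{missingness_shift}{vital-sign recording rate steps
#'     `recorded_from` to `recorded_to` at `t_star`.}
#'   \item{category_emergence}{a new level (`level`, default `"covid19"` on
#'     `attendance_complaint`) appears at `t_star` with probability mass
#'     `mass` taken proportionally from existing levels, carrying log-odds
#'     `coef`.}
#'   \item{concept_shift}{the coefficient of `feature` (default `resp_rate`)
#'     is replaced by `new_beta` (default the sign flip) at `t_star`; the
#'     covariate marginals are untouched.}
#'   \item{covid_like}{covariate shift (walk-in collapse) + prevalence shift
#'     + missingness shift (more vitals recorded) + category emergence,
#'     with weekly volume halved from `t_star`.}
#' }
#'
#' @param kind one of `"baseline"`, `"covariate_shift"`, `"prevalence_shift"`,
#'   `"missingness_shift"`, `"category_emergence"`, `"concept_shift"`,
#'   `"covid_like"`.
#' @param ... overrides: `horizon_weeks` (default 52), `weekly_volume`
#'   (default 1500; scalar or per-week vector), `t_star` (default 40),
#'   `base_admission_rate` (default 0.30), `vitals_recorded_rate` (default
#'   0.65), `history_linkage` (default 0.55, the fraction of attendances with
#'   a linked prior history), `start_date` (default 2019-04-01, a Monday),
#'   and the family-specific parameters listed above. `numeric_specs`,
#'   `categorical_specs`, `history_specs` replace whole spec blocks.
#' @return a `scenario_config` object.
#' @export
#' @examples
#' sc <- make_scenario("baseline", horizon_weeks = 8, weekly_volume = 100)
#' ep <- simulate_cohort(sc, seed = 1)
#' mean(ep$outcome)
make_scenario <- function(kind = "baseline", ...) {
  stop_if(!kind %in% .scenario_kinds,
          "unknown scenario kind: ", kind)
  ov <- list(...)
  sc <- list(
    kind = kind,
    horizon_weeks = ov$horizon_weeks %||% 52L,
    weekly_volume = ov$weekly_volume %||% 1500L,
    start_date = as.Date(ov$start_date %||% "2019-04-01"),
    base_admission_rate = ov$base_admission_rate %||% 0.30,
    vitals_recorded_rate = ov$vitals_recorded_rate %||% 0.65,
    history_linkage = ov$history_linkage %||% 0.55,
    numeric_specs = ov$numeric_specs %||% .numeric_defaults(),
    categorical_specs = ov$categorical_specs %||% .categorical_defaults(),
    history_specs = ov$history_specs %||% .history_defaults(),
    drift_events = list()
  )
  t_star <- as.integer(ov$t_star %||% 40L)

  ev <- function(kind, ...) c(list(kind = kind, t_star = t_star), list(...))
  sc$drift_events <- switch(kind,
    baseline = list(),
    covariate_shift = list(ev("covariate_shift",
      feature = ov$feature %||% "arrival_mode",
      new_probs = ov$new_probs %||% .walkin_probs(
        sc, ov$walkin_from %||% 0.6, ov$walkin_to %||% 0.2))),
    prevalence_shift = list(ev("prevalence_shift",
      delta = ov$delta %||% .delta_for_rate(sc, ov$rate_to %||% 0.5))),
    missingness_shift = list(ev("missingness_shift",
      recorded_to = ov$recorded_to %||% 0.85)),
    category_emergence = list(ev("category_emergence",
      feature = ov$feature %||% "attendance_complaint",
      level = ov$level %||% "covid19",
      mass = ov$mass %||% 0.30,
      coef = ov$coef %||% 2.5)),
    concept_shift = {
      feat <- ov$feature %||% "resp_rate"
      old <- sc$numeric_specs[[feat]]$beta
      list(ev("concept_shift", feature = feat,
              new_beta = ov$new_beta %||% -old))
    },
    covid_like = list(
      ev("covariate_shift", feature = "arrival_mode",
         new_probs = .walkin_probs(sc, 0.6, 0.2)),
      ev("prevalence_shift",
         delta = ov$delta %||% .delta_for_rate(sc, ov$rate_to %||% 0.5)),
      ev("missingness_shift", recorded_to = ov$recorded_to %||% 0.85),
      ev("category_emergence", feature = "attendance_complaint",
         level = "covid19", mass = ov$mass %||% 0.30,
         coef = ov$coef %||% 2.5))
  )
  if (kind == "covid_like") {
    v <- rep_len(sc$weekly_volume, sc$horizon_weeks)
    if (t_star < sc$horizon_weeks)
      v[(t_star + 1):sc$horizon_weeks] <-
        round(v[(t_star + 1):sc$horizon_weeks] * (ov$volume_factor %||% 0.5))
    sc$weekly_volume <- v
  }
  # merge any extra drift events supplied directly
  if (!is.null(ov$drift_events)) sc$drift_events <- c(sc$drift_events, ov$drift_events)
  class(sc) <- "scenario_config"
  validate_scenario(sc)
  sc
}

# Intercept step that moves the marginal admission rate to `rate_to`.
.delta_for_rate <- function(sc, rate_to) {
  scenario_intercept(sc, rate_to) - scenario_intercept(sc)
}

# Rescale arrival-mode probabilities to a target walk-in fraction, keeping the
# relative mix of the other modes.
.walkin_probs <- function(sc, from, to) {
  p <- sc$categorical_specs$arrival_mode$probs
  other <- p[names(p) != "walk_in"]
  c(walk_in = to, other / sum(other) * (1 - to))
}

validate_scenario <- function(sc) {
  stop_if(sc$horizon_weeks < 1, "horizon must be at least one week")
  stop_if(any(rep_len(sc$weekly_volume, sc$horizon_weeks) < 0),
          "weekly volume must be non-negative")
  stop_if(sc$vitals_recorded_rate < 0 || sc$vitals_recorded_rate > 1,
          "vitals_recorded_rate must lie in [0, 1]")
  stop_if(sc$history_linkage < 0 || sc$history_linkage > 1,
          "history_linkage must lie in [0, 1]")
  for (nm in names(sc$categorical_specs)) {
    spec <- sc$categorical_specs[[nm]]
    stop_if(abs(sum(spec$probs) - 1) > 1e-8,
            "level probabilities of ", nm, " must sum to 1")
    stop_if(!setequal(names(spec$probs), names(spec$coefs)),
            "probs/coefs level mismatch in ", nm)
  }
  for (e in sc$drift_events) {
    stop_if(!e$kind %in% .drift_kinds, "unknown drift event kind: ", e$kind)
    stop_if(e$t_star < 0 || e$t_star >= sc$horizon_weeks,
            "drift onset week ", e$t_star, " outside horizon")
  }
  invisible(sc)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$kind, "\n")
  cat("  horizon:", x$horizon_weeks, "weeks from", format(x$start_date), "\n")
  cat("  weekly volume:", paste(unique(rep_len(x$weekly_volume, x$horizon_weeks)),
                                collapse = "/"), "\n")
  cat("  base admission rate:", x$base_admission_rate,
      " vitals recorded:", x$vitals_recorded_rate, "\n")
  if (length(x$drift_events))
    for (e in x$drift_events)
      cat("  drift:", e$kind, "at week", e$t_star, "\n")
  invisible(x)
}

# Instantaneous parameters ---------------------------------------------------

# Apply every drift event with onset <= t (step functions) and return the
# parameter set in force at week t.
scenario_params_at <- function(sc, t) {
  p <- list(
    numeric = sc$numeric_specs,
    categorical = sc$categorical_specs,
    history = sc$history_specs,
    recorded = sc$vitals_recorded_rate,
    delta0 = 0
  )
  for (e in sc$drift_events) {
    if (t < e$t_star) next
    p <- switch(e$kind,
      covariate_shift = {
        if (e$feature %in% names(p$numeric)) {
          if (!is.null(e$new_mean)) p$numeric[[e$feature]]$mean <- e$new_mean
          if (!is.null(e$new_sd)) p$numeric[[e$feature]]$sd <- e$new_sd
        } else {
          probs <- e$new_probs[names(p$categorical[[e$feature]]$probs)]
          names(probs) <- names(p$categorical[[e$feature]]$probs)
          p$categorical[[e$feature]]$probs <- probs
        }
        p
      },
      prevalence_shift = { p$delta0 <- p$delta0 + e$delta; p },
      missingness_shift = { p$recorded <- e$recorded_to; p },
      category_emergence = {
        spec <- p$categorical[[e$feature]]
        spec$probs <- c(spec$probs * (1 - e$mass),
                        setNames(e$mass, e$level))
        spec$coefs <- c(spec$coefs, setNames(e$coef, e$level))
        p$categorical[[e$feature]] <- spec
        p
      },
      concept_shift = {
        if (e$feature %in% names(p$numeric)) {
          p$numeric[[e$feature]]$beta <- e$new_beta
        } else {
          p$categorical[[e$feature]]$coefs <- e$new_coefs
        }
        p
      })
  }
  p
}

# Mean and variance of the week-0 linear predictor (excluding intercept):
# numeric z-scores contribute beta^2 * P(recorded); categoricals their level
# coefficient mean/variance; history flags a Bernoulli(linkage * p) term.
.logit_moments <- function(sc) {
  p0 <- scenario_params_at(sc, 0)
  mu <- 0; s2 <- 0
  for (nm in names(p0$numeric)) {
    b <- p0$numeric[[nm]]$beta
    rec <- if (nm %in% .vital_names) p0$recorded else 1
    s2 <- s2 + b^2 * rec
  }
  for (s in p0$categorical) {
    cf <- s$coefs[names(s$probs)]
    m <- sum(s$probs * cf)
    mu <- mu + m
    s2 <- s2 + sum(s$probs * cf^2) - m^2
  }
  for (s in p0$history) {
    pe <- sc$history_linkage * s$p
    mu <- mu + s$beta * pe
    s2 <- s2 + s$beta^2 * pe * (1 - pe)
  }
  list(mu = mu, s2 = s2)
}

# Baseline intercept: solves E[sigmoid(b0 + L)] = base_admission_rate with
# the linear predictor L treated as normal (CLT over many independent
# feature contributions); the realised marginal rate lands within ~0.005 of
# the target.
scenario_intercept <- function(sc, target = sc$base_admission_rate) {
  mo <- .logit_moments(sc)
  if (mo$s2 < 1e-12) return(logit(target) - mo$mu)
  marginal_rate <- function(b0)
    stats::integrate(function(z) sigmoid(b0 + mo$mu + sqrt(mo$s2) * z) *
                       stats::dnorm(z), -8, 8)$value
  stats::uniroot(function(b0) marginal_rate(b0) - target,
                 interval = logit(target) + c(-1, 1) * (abs(mo$mu) + 5),
                 tol = 1e-9)$root
}

# Episode simulation ----------------------------------------------------------

#' Simulate a cohort of ED attendances under a scenario
#'
#' Draws `n` attendances (default: the scenario's full weekly volume over its
#' horizon), with timestamps uniform within their week, numeric vitals
#' missing as a block when unrecorded, and outcomes drawn Bernoulli from the
#' scenario's true admission risk. Identical `(scenario, n, seed)` give
#' identical tables.
#'
#' @param scenario a `scenario_config`.
#' @param n total episode count; `NULL` uses the scenario's weekly volumes.
#' @param seed integer seed.
#' @return a data.frame episode table: `episode_id`, `timestamp` (POSIXct,
#'   UTC), `outcome` (1 = admitted), numeric features (NA = not recorded),
#'   categorical features (character), `hx_*` binary history flags, and
#'   `week` (0-based week index; derivable from the timestamp, kept for
#'   convenience).
#' @export
simulate_cohort <- function(scenario, n = NULL, seed = 1L) {
  validate_scenario(scenario)
  vols <- rep_len(scenario$weekly_volume, scenario$horizon_weeks)
  if (!is.null(n)) {
    stop_if(n < 0, "n must be non-negative")
    vols <- round(vols / sum(vols) * n)
    # distribute rounding remainder over the first weeks
    rem <- n - sum(vols)
    if (rem != 0) {
      idx <- seq_len(abs(rem))
      vols[idx] <- vols[idx] + sign(rem)
    }
  }
  with_seed(seed, {
    weeks <- rep(seq_along(vols) - 1L, vols)
    n_tot <- length(weeks)
    tab <- .simulate_rows(scenario, weeks)
    tab
  })
}

.simulate_rows <- function(sc, weeks) {
  n <- length(weeks)
  beta0 <- scenario_intercept(sc)
  num_names <- names(sc$numeric_specs)
  cat_names <- names(sc$categorical_specs)
  hx_names <- names(sc$history_specs)

  out <- data.frame(
    episode_id = sprintf("ep%07d", seq_len(n)),
    timestamp = as.POSIXct(sc$start_date, tz = "UTC") +
      weeks * 7 * 86400 + runif(n, 0, 7 * 86400 - 1),
    stringsAsFactors = FALSE
  )
  for (nm in num_names) out[[nm]] <- rep(NA_real_, n)
  for (nm in cat_names) out[[nm]] <- rep(NA_character_, n)
  for (nm in hx_names) out[[nm]] <- rep(0L, n)
  logits <- rep(beta0, n)

  for (t in unique(weeks)) {
    idx <- which(weeks == t)
    m <- length(idx)
    p <- scenario_params_at(sc, t)
    logits[idx] <- logits[idx] + p$delta0
    recorded <- runif(m) < p$recorded
    for (nm in num_names) {
      spec <- p$numeric[[nm]]
      z <- rnorm(m)
      x <- spec$mean + spec$sd * z
      if (nm %in% .vital_names) x[!recorded] <- NA_real_
      out[[nm]][idx] <- x
      logits[idx] <- logits[idx] +
        spec$beta * ifelse(is.na(x), 0, (x - spec$mean) / spec$sd)
    }
    for (nm in cat_names) {
      spec <- p$categorical[[nm]]
      lev <- sample(names(spec$probs), m, replace = TRUE, prob = spec$probs)
      out[[nm]][idx] <- lev
      logits[idx] <- logits[idx] + unname(spec$coefs[lev])
    }
    linked <- runif(m) < sc$history_linkage
    for (nm in hx_names) {
      spec <- p$history[[nm]]
      flag <- as.integer(linked & runif(m) < spec$p)
      out[[nm]][idx] <- flag
      logits[idx] <- logits[idx] + spec$beta * flag
    }
  }
  out$outcome <- as.integer(runif(n) < sigmoid(logits))
  out$week <- weeks
  # schema order: id, timestamp, outcome, numerics, categoricals, history
  out[, c("episode_id", "timestamp", "outcome", num_names, cat_names,
          hx_names, "week")]
}

#' True admission risk of a single episode under a scenario
#'
#' Evaluates the generator's ground-truth logistic mechanism
#' \eqn{\sigma(\beta_0(t) + \beta(t) \cdot \mathrm{encode}(x))} for one
#' episode at week `t`. Missing numerics contribute zero (the population
#' mean); categoricals contribute their level coefficient; history flags
#' their per-flag coefficient.
#'
#' @param record a one-row data.frame or named list with the scenario's
#'   features.
#' @param scenario a `scenario_config`.
#' @param t week index (0-based).
#' @return admission probability in (0, 1).
#' @export
true_risk <- function(record, scenario, t = 0L) {
  p <- scenario_params_at(scenario, t)
  lg <- scenario_intercept(scenario) + p$delta0
  for (nm in names(p$numeric)) {
    spec <- p$numeric[[nm]]
    x <- record[[nm]]
    if (!is.null(x) && !is.na(x)) lg <- lg + spec$beta * (x - spec$mean) / spec$sd
  }
  for (nm in names(p$categorical)) {
    spec <- p$categorical[[nm]]
    lev <- record[[nm]]
    if (is.null(lev) || is.na(lev)) next
    stop_if(!lev %in% names(spec$coefs),
            "unknown level '", lev, "' for ", nm, " at week ", t)
    lg <- lg + unname(spec$coefs[lev])
  }
  for (nm in names(p$history)) {
    x <- record[[nm]]
    if (!is.null(x) && !is.na(x)) lg <- lg + p$history[[nm]]$beta * x
  }
  unname(sigmoid(lg))
}

# Episode CSV I/O -------------------------------------------------------------

#' Write / read an episode table as CSV
#'
#' Fixed schema: `episode_id, timestamp (ISO-8601), outcome, <numerics>,
#' <categoricals>, hx_* flags[, cohort]`. Missing numerics are empty fields.
#'
#' @param table an episode table (see [simulate_cohort()]).
#' @param path file path.
#' @return `read_episodes` returns the episode table; `write_episodes`
#'   returns `path` invisibly.
#' @export
write_episodes <- function(table, path) {
  tab <- table
  tab$week <- NULL
  tab$timestamp <- format(tab$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  stop_if(!all(c("episode_id", "timestamp", "outcome") %in% names(tab)),
          "not an episode CSV: missing schema columns")
  tab$timestamp <- as.POSIXct(tab$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  stop_if(anyNA(tab$timestamp), "unparseable timestamps in ", path)
  hx <- grep("^hx_", names(tab))
  for (j in hx) tab[[j]][is.na(tab[[j]])] <- 0L
  tab
}
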