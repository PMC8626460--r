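---
title: "Drift surveillance for clinical admission models with exact Shapley attributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift surveillance for clinical admission models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The surveillance problem

A risk model deployed in an emergency department scores every attendance
for admission risk, but the stream it scores is not the stream it was
trained on. Two distinct failure modes threaten it:

* **data drift** — the distribution of input features changes,
  $P_t(x) \ne P_{t+t'}(x)$, e.g. walk-in attendances collapse during a
  pandemic wave, vital signs start being recorded for almost everyone, or a
  new complaint category appears in the record-keeping system;
* **concept drift** — the relationship between features and outcome
  changes, $P_t(y\mid x) \ne P_{t+t'}(y\mid x)$, e.g. admission decisions
  for the same presentation change under capacity pressure.

Performance tracking alone cannot separate the two. `shapdrift`
operationalises a complementary signal: per-attendance Shapley attributions
of the deployed model, normalised into importance *shares* and tracked in
weekly bins. Because the model is frozen, its attributions are a pure
function of the inputs it sees; a systematic movement of the share of a
feature is therefore direct evidence that the covariate stream feeding the
model has changed, and names the feature that changed. Conversely, a
degradation of ranking performance while every share is stable means the
model is using the same information in the same way yet ranking worse —
the feature–outcome relationship itself must have moved, which is the
signature of concept drift.

## Exact interventional Shapley attributions

For a tree-ensemble margin function $f$ (log-odds scale), an instance $x$
and a background set $Z$ of reference rows, the coalition value of a
feature subset $S$ is

$$v(S) = \frac{1}{|Z|}\sum_{z \in Z} f(x_S, z_{\bar S}),$$

the model's mean output when the features in $S$ take $x$'s values and all
others take background values (the "interventional" or
background-marginal convention; it is the only convention with an
unambiguous brute-force definition, which matters because the engine is
verified against one). The attribution of feature $i$ is the Shapley value

$$\phi_i = \sum_{S \subseteq F\setminus\{i\}}
  \frac{|S|!\,(d-|S|-1)!}{d!}\,\bigl[v(S\cup\{i\}) - v(S)\bigr],$$

and $\phi_0 = v(\emptyset)$ is the expected margin over the background. By
construction $\phi_0 + \sum_i \phi_i = f(x)$ (*local accuracy*); the
package enforces this identity to $10^{-8}$ on every explained row.

The exact engine exploits the tree structure. For one tree, one background
row $z$ and one leaf, the game restricted to that leaf is an AND-game: the
leaf is reached by the composite point iff every path feature that only
$x$ satisfies is in the coalition (set $D$) and every path feature that
only $z$ satisfies is outside it (set $E$); a path feature satisfied by
neither kills the leaf. The Shapley value of such an indicator game is
closed-form in $p=|D|$, $q=|E|$, and since a path of length $L$ admits only
$2^L$ routing patterns, background rows collapse into pattern counts per
leaf. After that precomputation the marginal cost per explained row is
$O(\text{trees} \times \text{leaves} \times \text{depth})$ — independent
of background size — which is why cohorts of tens of thousands of
episodes are explained in seconds. The test suite proves the engine equal
to the $2^d$ coalition enumeration to $10^{-8}$ over randomly fitted
ensembles, including instances and backgrounds with missing values.

**Attribution space.** Attributions are computed in margin (log-odds)
space, where tree-path arithmetic is exact. A probability-scale view
(`attribution_probability_scale()`) redistributes the sigmoid-scale change
per row for display; the normalised shares below are identical in either
space because they are per-row ratios of magnitudes.

## Normalised importance shares

Raw attribution magnitudes confound information change with outcome-scale
change: when the admission base rate rises, probability-scale magnitudes
inflate across the board. The tracked statistic is therefore the
per-attendance share

$$s_i = \frac{|\phi_i|}{\sum_j |\phi_j|},$$

which sums to one per attendance ($\phi_0$ is not a feature and is
excluded from the denominator). A row with all-zero attributions is given
the uniform share $1/d$ and flagged degenerate rather than dropped, so
cohort means stay defined. The package demonstrates the motivating
invariance directly: two cohorts sharing an identical covariate stream
whose outcomes are redrawn under an intercept shifted to move the
admission rate from 0.30 to 0.50, each with its own model fit, give
per-feature mean shares agreeing within 0.01 absolute while the mean
probability-scale attribution magnitude moves by roughly 30%.

## Flagging rules and the drift-type call

*Importance flags.* Weekly mean shares (Monday-anchored, half-open bins)
are compared against a bin-size-aware null: for a monitored bin of $n_b$
episodes, the reference period's pooled shares are resampled in groups of
$n_b$ (1000 bootstrap draws) and the central 99% interval taken. A feature
is flagged when its bin mean falls outside this interval, in a consistent
direction, for at least `k_consec = 2` consecutive bins. The interval is
deliberately 99% rather than 95%: roughly 18 features are scanned over
many weeks jointly, and the drift-type rule below needs the family-wise
false-flag rate to stay low; at these settings the realised per-feature
false-flag rate on stationary streams is far below the 10% the tests
require, while a walk-in collapse of the magnitude seen in a pandemic wave
(0.6 to 0.2) is flagged on the arrival-mode feature within one or two bins.

*Performance flags.* Weekly AUROC with percentile-bootstrap 95% CIs; a
week is flagged when its CI lies entirely below the pre-period reference
AUROC for two consecutive defined bins (one-sided — only degradation
argues for retraining). Because a small but sustained drop can sit inside
every weekly interval, the pipeline also pools the classification window
(default: the final 8 monitored weeks) into a single AUROC interval and
compares it against the reference — the same pre/during cohort contrast a
retrospective evaluation would make. Single-class weeks are reported as
undefined rather than failing.

*Drift typing.* Over the classification window:

| importance flags | performance flags | call |
|---|---|---|
| no  | no  | `stable` |
| yes | no  | `data_drift_no_degradation` |
| no  | yes | `concept_drift_suspected` |
| yes | yes | `data_drift_with_degradation` |

The call is a pure function of the two flag sets. It is an
operationalisation — a heuristic decision rule, not a sequential test with
formal error guarantees — and reports label it as such through the
provenance block.

## The synthetic attendance generator

Real ED extracts are not shareable, so the package ships a generator whose
defaults emulate a mid-size ED feed: 52 weeks of 1,500 attendances, a
baseline admission rate of 0.30, six numeric features (age plus five
triage vitals recorded as a block for 65% of attendances), four
categorical descriptors (arrival mode with a 60% walk-in fraction,
attendance/triage complaints, triage discriminator), and eight binary
condition-history flags linked for 55% of attendances. The admission
mechanism is logistic with per-SD coefficients on recorded numerics,
per-level coefficients on categoricals and per-flag history effects;
the intercept is solved numerically (normal approximation of the linear
predictor plus quadrature) so the marginal rate matches the configured
base rate. Coefficients were chosen so a boosted-tree model reaches an
AUROC in the mid-0.8s on held-out baseline data — the regime of published
ED admission models, where surveillance of a *strong* model is the
interesting problem.

Drift enters as step events at an onset week $t^\ast$: covariate shift
(walk-in collapse), prevalence shift (intercept step, parameterised by the
target during-period rate, default 0.50), missingness shift (vitals
recording rises to 85%), category emergence (a new complaint level taking
30% of post-onset mass proportionally from existing levels, carrying +2.5
log-odds — an emergent severe respiratory illness that the frozen encoder
can only map to its prior), and concept shift (a coefficient sign flip
with untouched marginals). The `covid_like` family combines the first
four and halves attendance volume from onset. Together these reproduce
the canonical pandemic-onset signature: attendance collapse driven by
walk-ins, admission-rate jump, vitals-recording uptick, an emergent
complaint category, and a sustained AUROC drop of roughly 0.03–0.05
produced mechanically by the emergent category (whose true risk signal is
invisible to the frozen encoding) and the compressed arrival-mode mix.

All randomness flows from a single integer seed; a function needing $k$
independent substreams uses `seed`, `seed + 1`, …, `seed + k - 1`, and
every seeded function restores the caller's RNG state. Identical
`(scenario, n, seed)` yield byte-identical tables.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: numeric features are drawn
independently (real vitals are strongly correlated, which interventional
conditioning would expose as off-manifold composites), there is no
seasonality or weekday structure, drift transitions are steps rather than
ramps, and level vocabularies are small. The generator validates the
surveillance *machinery*; it does not certify performance on any
particular hospital's stream.

## Numerical and design decisions

* **Target encoding** uses additive smoothing
  $(n_l\bar y_l + m\bar y)/(n_l + m)$ with default $m = 10$; the smoothing
  weight is documented rather than claimed optimal. Maps are fitted on the
  training cohort only and frozen; unseen levels map to the prior *and*
  surface as logged new-category events, because an emergent category is
  itself a drift observable.
* **Split comparisons in single precision.** The boosting backend stores
  features and thresholds as float32; the traversal kernels compare
  `(float)x < (float)threshold` so extracted trees route identically to
  the backend. The round-trip fidelity check at fit time additionally
  replicates the backend's float32 accumulation order and requires
  agreement within $10^{-6}$; routine prediction accumulates in double.
* **Hyperparameters** default to 200 trees, depth 4, learning rate 0.1,
  subsample 0.8, column subsample 0.8, fit single-threaded for exact
  reproducibility. A small k-fold grid-search helper is provided; no claim
  is made that the defaults are tuned.
* **Background set**: 256 training rows under a fixed seed by default. The
  attribution expectation baseline is part of the model-surveillance
  contract, so it is serialised alongside reports via the provenance
  block.
* **Ties and conventions**: AUROC credits ties one half (Mann–Whitney);
  average precision is the step-sum over descending unique scores; the
  fixed-recall threshold is the largest cut whose recall reaches the
  target; weekly bins are Monday-anchored and half-open, and a record on a
  split boundary joins the later period.
* **Bootstrap**: percentile intervals, 1000 resamples by default, seeded
  per bin (`seed + week`); resamples on which a statistic is undefined
  (single-class AUROC draws) are skipped and counted.
* **Degenerate inputs**: empty weeks are reported with $n = 0$;
  single-class weeks carry `NA` AUROC; all-zero attribution rows are
  flagged, not fatal; a single-leaf tree attributes nothing and
  contributes only to $\phi_0$.

## Problem sizes used in validation

The shipped tests validate the engine oracle on 20 random ensembles (up to
10 features, 50 trees, depth 4), local accuracy and share conservation on
a 1,000-row cohort, the prevalence-invariance contrast on two 20,000-row
cohorts, flagging operating characteristics on 20 seeds of 24-week
streams at 400 attendances/week, and drift typing on 20 seeds of 36-week
streams; the acceptance script additionally runs the full 52-week,
1,500-attendances/week scenario end to end. These sizes were chosen as the
smallest at which the binomial and bootstrap arithmetic of the rules is
meaningfully exercised.

## Known limitations

* The drift-type rule is qualitative: "concept drift suspected" means
  degradation without attribution movement, not a formal test of
  $P(y\mid x)$ change.
* Interventional conditioning evaluates the model on feature combinations
  that may be off-manifold for strongly dependent features.
* Bootstrap intervals are percentile, not studentised; for weeks with very
  few admissions they can undercover.
* The probability-scale attribution view distributes the sigmoid
  nonlinearity proportionally across features; it is a display convention,
  and all tracked statistics use margin-space magnitudes or shares.
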