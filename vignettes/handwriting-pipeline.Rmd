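---
title: "From pen samples to item-level handwriting norms: the penmetrics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pen samples to item-level handwriting norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penmetrics)
```

## The measurement problem

Handwriting-to-dictation experiments on pressure digitizer tablets record a
stream of pen samples — timestamp, x/y position, pen pressure — at a fixed
sampling rate (200 Hz, i.e. one sample every 5 ms, is typical of Wacom-class
hardware). For logographic scripts such as Chinese, the written character is
hierarchically organized: a character contains radicals, radicals contain
strokes, and writers follow conventional stroke order. The scientific
questions in this area ("do lexical variables cascade from whole-character
preparation down to stroke execution, and with what attenuation?") therefore
require metrics at three nested unit levels. `penmetrics` turns raw pen
streams into those metrics and runs the item-level statistics that
large-scale handwriting norm studies report.

## The unit model and its metrics

A **stroke** is a maximal run of consecutive samples with pressure > 0;
zero-pressure samples are the pen-in-air (hover) trace, which is kept for
rendering but contributes to no metric. Stroke onset and offset are the
timestamps of the run's first and last sample; no velocity-based refinement
is applied, because pressure alone defines paper contact on these devices.
The minimum stroke size is one sample by default (`min_stroke_samples`
raises it if a noisy digitizer produces one-sample blips).

**Radicals** have no pen events of their own: strokes are grouped into
radicals through a character decomposition table (character → ordered
per-radical stroke counts), with radical k receiving the next `counts[k]`
detected strokes in writing order. If the detected stroke count disagrees
with the decomposition, the trial is flagged `decomposition_mismatch` and
its radical level is skipped — stroke- and character-level metrics are still
computed. Grouping is never inferred from the ink.

Per unit the pipeline computes:

* **latency** — for the character, time from the offset of the auditory
  prompt to the first paper contact; for radicals and strokes, the gap from
  the previous unit's offset to the current unit's onset. Inter-unit
  latency is undefined for the *first* radical/stroke (there is no previous
  unit); the character latency covers preparation of the first unit, and
  first-unit cells are excluded from radical/stroke aggregates rather than
  coded as zero.
* **duration** — first to last sample of the unit (for the character, first
  paper contact to the last inked sample of the trial).
* **length** — sum of Euclidean distances between consecutive samples along
  each stroke; radical and character lengths are sums of their strokes'
  lengths, so length is conserved across levels by construction.
* **mean pressure** — sample-weighted mean over the unit's inked samples.
  Hover samples are excluded even at the character level: including
  pressure-0 samples would dilute the mean with values that measure nothing
  about paper contact.
* **distance** (radical/stroke only) — straight-line jump from the previous
  unit's end point to the current unit's start point.

Times are milliseconds, session-relative; coordinates and pressure stay in
device units (the y axis grows downward, screen-style, and is flipped only
for display). Coordinates are not resampled or smoothed before length
computation — with equal-interval sampling, smoothing would change lengths
by an uncontrolled, device-dependent amount.

These definitions force two identities that the test suite asserts on every
synthetic trial: character length equals the sum of radical lengths equals
the sum of stroke lengths (when grouping succeeds), and character duration
equals the sum of stroke durations plus the inter-stroke gaps.

## Response coding and exclusions

Participants self-report each trial with the response keys 0 (correct), 1
(character amnesia: the character was known but its form could not be
retrieved) or 2 (don't know, written as a circle in the grid). Raters
independently code each penscript correct/incorrect and flag revisions;
with several raters the majority wins and even ties break conservatively to
incorrect. The self-report/rater consistency rate and a two-way
random-effects, absolute-agreement, single-rater ICC — ICC(A,1), with the
standard F-based confidence interval — summarize coding quality. ICC(A,1)
is the appropriate variant when every penscript is coded by interchangeable
raters drawn from a pool and absolute agreement (not mere consistency) is
the question; the rater table carries no identity structure that would
justify a mixed-effects variant.

Only rater-correct, unrevised trials enter the metric analyses. Amnesia
rates are computed from self-reports *before* those exclusions (an amnesia
trial has no valid character to time), with don't-know trials removed from
the denominator by default (`amnesia_denominator` switches to all trials).

Outlier rules then remove, at the character level, latencies longer than
10 s and durations shorter than 1 s or longer than 10 s; at the radical and
stroke levels, latencies and durations longer than 2 s. All bounds are
strict (a value exactly at a bound is kept). Removal is **per metric**, not
per unit: an excluded latency leaves the same unit's duration in place.
This is deliberate — latency and duration can show different exclusion
rates at the same level, which per-trial removal could not produce. The
`exclusion_result` report carries counts and percentages per level ×
metric, and the filter is idempotent. Exclusions are applied at trial level
before item aggregation (aggregating first would let a single extreme trial
contaminate an item mean that then survives filtering).

## Item-level aggregation and the statistical battery

Analyses collapse to one row per unique character: radical- and
stroke-level metrics are first averaged within each trial across that
trial's units, then across participants; character metrics average across
participants directly. This keeps the character as the unit of analysis at
all three levels, so one set of lexical predictors can be used throughout.

The battery consists of:

* **Split-half reliability** — participants split at random into two equal
  halves (odd counts drop one at random, reported), item vectors computed
  per half, Pearson-correlated across items, and stepped up with the
  Spearman–Brown prophecy formula 2r/(1+r). The split is seeded; there is
  no canonical split, so the seed is an explicit argument.
* **Correlations** — Pearson over complete pairs; for two sum-coded ±0.5
  binary variables this equals the phi coefficient, so no separate
  estimator is needed. Stars at .05/.01/.001.
* **Collinearity screening** — stepwise VIF: each predictor's VIF is
  1/(1−R²) from regressing it on the others; the largest is dropped until
  all fall below the threshold (default 5). Exact collinearity (infinite
  VIF) drops one member with a warning, ties breaking alphabetically so the
  procedure is deterministic.
* **Regression battery** — OLS of each item-level outcome on the 14 lexical
  predictors, all z-transformed on the analysis sample after exclusions
  (binary sum-coded predictors included — z-scoring every predictor puts
  all coefficients on a per-SD footing). Execution-side outcomes carry
  mechanical covariates (e.g. character duration is adjusted for character
  length, stroke distance and stroke latency; see `default_covariates()`),
  themselves z-scored but exempt from the multiplicity correction.
  Benjamini–Hochberg FDR at q = .05 is applied within one model over the
  family of the 14 predictor terms; per-model families are the conventional
  reading when a correction is said to apply "in all regression analyses",
  and intercept/covariates are nuisance terms, not hypotheses. Both raw and
  BH-adjusted p-values are reported, since published tables are often
  ambiguous about which they print.
* **Cross-level contrasts** — for a pair of levels (character vs. radical,
  character vs. stroke, radical vs. stroke; three separate models per
  outcome) the item-level outcome is stacked long, Level is coded −0.5/+0.5
  (higher level positive), and the model adds Level and all
  Level × predictor interactions. With this coding the Level coefficient is
  the between-level difference and each interaction is the between-level
  difference of that predictor's effect — the quantity of interest under a
  cascaded-attenuation account. Duration contrasts add the level-specific
  trace length and its Level interaction as covariates, because longer ink
  trivially takes longer to produce. The FDR family here is the 14 main
  effects plus their 14 interactions.

Weighted least squares (weighting items by trials-per-item) was considered
and rejected: item-level norm studies report plain OLS on item means, and
the trial counts are nearly balanced by design.

## The synthetic experiment generator

`simulate_dataset()` produces every input the pipeline consumes — pen
streams, event logs, rater codes, decomposition table, lexical norms — plus
the ground truth that generated them. Its defaults emulate the conditions
of a 200-Hz, 42-participant, handwriting-to-dictation study at published
scale: character latency centred near 1032 ms, radical-boundary and
inter-stroke gaps near 151 and 113 ms, stroke durations near 148 ms, pen
pressure near 12,500 device units, stroke lengths near 5 coordinate units,
5–21 strokes per character (mean ≈ 9.7) over 1–7 radicals, and an amnesia
base rate near 5%.

Latencies, gaps and durations are drawn from shifted log-normals — they are
positive and right-skewed, with means far below their maxima, which is the
qualitative shape reported for such data; no distributional family is ever
stated in norm papers, so the log-normal is a modelling choice, not a
reproduction. Designed lexical effects enter as additive shifts through the
z-scored predictors (`beta_*` arguments, ms per SD; defaults follow the
published character/radical/stroke coefficient profiles), alongside item
and participant random intercepts — the minimal random-effect structure
that makes split-half reliability nontrivial. Amnesia responses follow a
logistic model on the z-scored predictors; don't-know trials are drawn as
circles; rater codes disagree with the self-report's implied correctness
with a small probability and revisions are flagged at the published rates.

All timing is snapped to the sampling grid, so a 150-ms stroke at a 5-ms
interval spans exactly 31 samples and measures exactly 150 ms; hover
samples fill the gaps (plus a 3-sample approach before the first stroke)
and the decomposition's stroke count is realized exactly as
pressure-positive runs. Everything is deterministic given the config seed.

What the generator does **not** emulate: real glyph geometry (strokes are
schematic random polylines — every metric depends only on coordinates and
timestamps, not legibility), correlated lexical predictors (they are drawn
independently at the published marginal scales), revision/crossing-out ink,
within-character structure effects (an early complex radical does not slow
a later one), and speed–accuracy trade-offs (amnesia is independent of
latency given the item). Passing tests on this generator therefore
establish that the *pipeline* measures what it claims exactly and recovers
designed effect structure without bias — not that real pen data are
log-normal or that real predictors are orthogonal.

## Numerical and design notes

* Degenerate inputs: an empty stream yields zero strokes (not an error); a
  trial with no ink gets a flagged `no_ink` record with missing metrics; a
  single-point stroke has length 0; a single-radical tree has no radical
  latency/distance; constant rater tables make the ICC undefined (error).
* The tie-break toward "incorrect" in majority rater coding is
  conservative: a disputed penscript is excluded rather than analysed.
* `spearman_brown()` rejects r = −1 (the correction has a pole there).
* Stroke distance runs from the previous stroke's **end** to the current
  stroke's **start** — the jump the pen actually makes.
* In cross-level models the predictors are z-scored on the stacked
  (two-rows-per-item) sample; this differs from per-level scaling by a
  factor of about 1 + 1/(4n) and keeps one scale for main effects and
  interactions.
* Parameter-recovery checks in the test suite run 100 replicates at 10
  participants × 200 items — large enough that Monte-Carlo standard errors
  are a few ms against designed effects of 20–150 ms, small enough to run
  on one CPU alongside the rest of the suite; the acceptance script uses 42
  participants × 300 items for its single full-pipeline run.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(n_participants = 10, n_items = 200, seed = 7)
sim <- simulate_dataset(cfg)

metrics <- extract_metrics(sim$samples, sim$events, sim$decomposition)
codes <- code_responses(sim$events, sim$raters)
qc <- apply_metric_exclusions(
  metrics[metrics$trial_id %in% filter_analysis_trials(codes), ])
items <- aggregate_items(qc$records, sim$events)

fit <- fit_item_regression(items, sim$norms, "character_latency")
print(fit)
contrast <- fit_level_contrast(items, sim$norms, "latency",
                               c("character", "radical"))
```

The same flow starting from files on disk replaces the first block with
`read_pen_samples()`, `read_events()`, `read_decomposition()` and
`read_lexical_norms()`; `inst/cli/penmetrics.R` wraps both directions for
shell use.

## Known limitations

The pipeline analyses item means, not trial-level mixed models; it does not
check stroke-order correctness or discover radicals from ink; kinematics
beyond the unit metrics (velocity, jerk) are out of scope; and rendering is
diagnostic, not typographic. Reliability and recovery results quoted above
are properties of the synthetic study conditions — real data with
correlated predictors will show higher VIFs and different reliability than
the orthogonal-predictor simulation.
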