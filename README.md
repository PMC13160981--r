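# penmetrics

Stroke-level handwriting metrics and item-level analysis for pen-tablet
dictation experiments.

Pressure digitizer tablets record handwriting as a stream of pen samples —
timestamp *t* (ms), position *(x, y)*, pressure *p* — at a fixed rate
(typically 200 Hz). For hierarchical scripts such as Chinese, where a
character is composed of radicals and radicals of strokes, research on
handwriting production needs timing, geometry and pressure measures at all
three unit levels. `penmetrics` is the analysis core for such experiments:

* **Segmentation** — a stroke is a maximal run of samples with *p* > 0;
  zero-pressure samples are the pen-in-air trace. Strokes are grouped into
  radicals via a character decomposition table (ordered per-radical stroke
  counts), never inferred from the ink.
* **Metrics** — per character, radical and stroke: writing latency
  (stimulus offset → first contact for the character; previous unit's
  offset → current onset for sub-units), writing duration, trace length
  (Σ of inter-sample Euclidean distances), mean pen pressure over inked
  samples, and inter-unit jump distance. Definitions force the conservation
  identities *length(character) = Σ length(radicals) = Σ length(strokes)*
  and *duration(character) = Σ durations + Σ inter-stroke gaps*, which the
  test suite asserts on every synthetic trial.
* **QC** — self-report vs. rater coding with a consistency rate and an
  inter-rater ICC(A,1) with F-based CI; retention of rater-correct,
  unrevised trials; per-metric outlier rules (character latency > 10 s,
  duration outside [1 s, 10 s]; sub-unit latency/duration > 2 s) with an
  auditable exclusion report.
* **Item statistics** — aggregation to one row per character (sub-unit
  metrics averaged within trial, then across participants); split-half
  reliability with the Spearman–Brown correction 2r/(1+r); Pearson/phi
  correlation matrices; stepwise VIF screening (VIF = 1/(1−R²),
  threshold 5); OLS regression of each outcome on 14 z-scored lexical
  predictors with Benjamini–Hochberg FDR (q = .05) over the predictor
  family; and cross-level contrast models with Level (±0.5) × predictor
  interactions for testing cascaded attenuation of lexical effects.
* **Simulation** — a generator that produces complete synthetic
  experiments (pen streams, events, rater codes, decomposition, norms)
  with configurable ground-truth effects, so the entire pipeline is
  testable at desk scale.
* **Rendering** — penscript images (`<participant>_<item>_<char>.png`) and
  per-stroke diagnostic panels annotated with each stroke's metrics.

## Worked example

```r
library(penmetrics)

cfg <- sim_config(n_participants = 10, n_items = 200, seed = 7)
sim <- simulate_dataset(cfg)

metrics <- extract_metrics(sim$samples, sim$events, sim$decomposition)
codes <- code_responses(sim$events, sim$raters)
print(codes)
#> <penscript_codes> 2000 trials; self-report/rater consistency 98.25%

qc <- apply_metric_exclusions(
  metrics[metrics$trial_id %in% filter_analysis_trials(codes), ])
items <- aggregate_items(qc$records, sim$events)

fit <- fit_item_regression(items, sim$norms, "character_latency")
round(coef(fit)[c("frequency", "age_of_acquisition", "word_familiarity")], 1)
#>          frequency age_of_acquisition   word_familiarity
#>             -151.3              133.3             -114.2
fit$r_squared
#> [1] 0.656
```

The printed coefficients are in ms per SD of each predictor: with the
generator's default effect structure, higher-frequency characters are
initiated ~151 ms faster per SD of log frequency, later-acquired ones
~133 ms slower, and characters from more familiar context words ~114 ms
faster — the designed values are −158, +121 and −105, inside the fit's
standard errors. `print(fit)` lists every term with β, t, raw and
FDR-adjusted p, and a significance flag.

A thin command-line front end (`inst/cli/penmetrics.R`) exposes
`simulate`, `extract`, `qc`, `aggregate`, `regress` and `render`
subcommands over the same functions for file-based use.

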