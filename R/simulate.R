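#' Configuration for the synthetic handwriting-experiment generator
#'
#' Defaults emulate the conditions of a 200-Hz pen-tablet
#' handwriting-to-dictation study: 42 participants x 1200 characters, 5-ms
#' sampling interval, item-level character latency around 1032 ms, radical
#' and stroke inter-unit gaps around 151 and 113 ms, stroke durations around
#' 148 ms, pen pressure around 12,500 device units, stroke trace lengths
#' around 5 coordinate units, and an amnesia base rate near 5%. Latencies,
#' gaps and durations are drawn from shifted log-normal distributions
#' (positive and right-skewed); designed lexical effects enter as additive
#' shifts on the z-scored predictors, alongside participant and item random
#' intercepts.
#'
#' @param n_participants,n_items Design size.
#' @param seed Integer seed; mandatory, every draw of the generator is
#'   deterministic given it.
#' @param sampling_interval_ms Digitizer sampling period (5 ms = 200 Hz).
#' @param beta_char_latency,beta_radical_latency,beta_stroke_latency,beta_stroke_duration
#'   Named numeric vectors of designed effects (ms per SD of each predictor)
#'   applied to the character latency, radical-boundary gaps, inter-stroke
#'   gaps, and stroke durations. Partial vectors are allowed; unnamed
#'   predictors get 0.
#' @param char_latency_base Mean character latency (ms).
#' @param sigma_item,sigma_participant SDs of item and participant random
#'   intercepts on character latency (ms).
#' @param resid_sdlog Log-scale SD of the right-skewed residual on character
#'   latency.
#' @param resid_mean Mean of the (centred) character-latency residual
#'   component before centring (ms).
#' @param stroke_gap_mean,radical_gap_mean,stroke_dur_mean Means (ms) of the
#'   log-normal inter-stroke gaps, radical-boundary gaps and stroke
#'   durations.
#' @param gap_sdlog,dur_sdlog Log-scale SDs of gaps and durations.
#' @param pressure_mean,pressure_sd Pen pressure distribution (device units).
#' @param stroke_len_mean,stroke_len_sd Stroke trace length (coordinate
#'   units).
#' @param stroke_dist_mean,stroke_dist_sd Start-point jump between
#'   consecutive strokes within a radical.
#' @param radical_dist_mean,radical_dist_sd Jump at radical boundaries.
#' @param amnesia_intercept Logit-scale intercept of the amnesia model
#'   (default `qlogis(0.05)`).
#' @param amnesia_slopes Named logit-scale slopes on z-scored predictors.
#' @param p_dont_know Probability of a "don't know" (circle) response.
#' @param p_rater_inconsistent Probability that a rater code disagrees with
#'   the self-report's implied correctness.
#' @param p_revised Probability a correct penscript is flagged as revised.
#' @param n_raters Raters per penscript.
#' @param n_strokes_range,n_radicals_max Decomposition limits.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 42L, n_items = 1200L, seed,
                       sampling_interval_ms = 5,
                       beta_char_latency = c(
                         phonogram = 1.416, phonetic_radical_order = 71.385,
                         regularity = -3.452, homophone_density = 25.764,
                         n_meanings = 11.878, imageability = -12.703,
                         concreteness = -48.257, frequency = -158.005,
                         age_of_acquisition = 121.499, n_strokes = 51.338,
                         n_radicals = -6.365, left_right = -73.977,
                         top_down = -66.401, word_familiarity = -105.341),
                       beta_radical_latency = c(
                         phonogram = -5.338, phonetic_radical_order = 13.961,
                         regularity = 0.303, homophone_density = -1.532,
                         n_meanings = -2.050, imageability = 2.890,
                         concreteness = 1.769, frequency = -7.408,
                         age_of_acquisition = 7.500, n_strokes = 10.628,
                         n_radicals = -5.866, left_right = -11.249,
                         top_down = -2.484, word_familiarity = -2.220),
                       beta_stroke_latency = c(
                         phonogram = 0.236, phonetic_radical_order = -1.063,
                         regularity = -0.752, homophone_density = 0.738,
                         n_meanings = 0.352, imageability = 0.462,
                         concreteness = 1.361, frequency = -3.471,
                         age_of_acquisition = 3.299, n_strokes = 0.630,
                         n_radicals = 2.002, left_right = -22.340,
                         top_down = -19.427, word_familiarity = 0.907),
                       beta_stroke_duration = c(
                         phonogram = -2.885, phonetic_radical_order = 0.556,
                         regularity = 0.644, homophone_density = -0.449,
                         n_meanings = -0.509, imageability = 1.120,
                         concreteness = -1.399, frequency = 0.148,
                         age_of_acquisition = 0.109, n_strokes = 5.702,
                         n_radicals = 0.044, left_right = -2.845,
                         top_down = 3.273, word_familiarity = -0.876),
                       char_latency_base = 1032,
                       sigma_item = 200, sigma_participant = 100,
                       resid_sdlog = 0.6, resid_mean = 250,
                       stroke_gap_mean = 113, radical_gap_mean = 151,
                       stroke_dur_mean = 148, gap_sdlog = 0.3,
                       dur_sdlog = 0.2,
                       pressure_mean = 12500, pressure_sd = 800,
                       stroke_len_mean = 5, stroke_len_sd = 1.2,
                       stroke_dist_mean = 2.5, stroke_dist_sd = 0.5,
                       radical_dist_mean = 3.8, radical_dist_sd = 1.0,
                       amnesia_intercept = stats::qlogis(0.05),
                       amnesia_slopes = c(frequency = -0.5,
                                          age_of_acquisition = 0.6,
                                          n_strokes = 0.35,
                                          regularity = -0.15,
                                          word_familiarity = -0.3),
                       p_dont_know = 0.01,
                       p_rater_inconsistent = 0.0238,
                       p_revised = 0.027, n_raters = 1L,
                       n_strokes_range = c(5L, 21L), n_radicals_max = 7L) {
  if (missing(seed)) stop("sim_config() requires an explicit seed")
  if (sampling_interval_ms <= 0) stop("sampling_interval_ms must be > 0")
  sds <- c(sigma_item, sigma_participant, resid_sdlog, gap_sdlog, dur_sdlog,
           pressure_sd, stroke_len_sd, stroke_dist_sd, radical_dist_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  probs <- c(p_dont_know, p_rater_inconsistent, p_revised)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(stroke_gap_mean, radical_gap_mean, stroke_dur_mean) <= 0))
    stop("gap and duration means must be > 0")
  cfg <- as.list(environment())
  cfg$sds <- NULL; cfg$probs <- NULL
  full_beta <- function(b) {
    out <- stats::setNames(numeric(14), lexical_predictors())
    out[names(b)] <- b
    out
  }
  for (nm in c("beta_char_latency", "beta_radical_latency",
               "beta_stroke_latency", "beta_stroke_duration"))
    cfg[[nm]] <- full_beta(cfg[[nm]])
  cfg$amnesia_slopes <- full_beta(cfg$amnesia_slopes)
  structure(cfg, class = "sim_config")
}

# log-normal with target mean m and log-sd s (internal)
rlnorm_mean <- function(n, m, s) stats::rlnorm(n, log(m) - s^2 / 2, s)

# snap durations/gaps onto the sampling grid (internal)
snap <- function(t, interval) pmax(interval, round(t / interval) * interval)

#' Simulate the stimulus side: decomposition table and lexical norms
#'
#' Characters are synthetic code points; decompositions are random
#' compositions of the stroke count into radicals; the 14 predictors are
#' drawn to the scale of published character norms (binary factors as
#' sum-coded Bernoulli draws, continuous ones as clipped normals). Stroke
#' and radical counts in the norms always equal the decomposition's.
#'
#' @param config A [sim_config()].
#' @return List with `decomposition`, `norms`, and `z` (the item x predictor
#'   matrix of z-scored predictors the designed effects act through).
#' @export
simulate_norms <- function(config) {
  n <- config$n_items
  chars <- vapply(seq_len(n) - 1L, function(i) intToUtf8(0x4E00 + i),
                  character(1))
  ns <- pmin(config$n_strokes_range[2],
             pmax(config$n_strokes_range[1],
                  round(stats::rnorm(n, 9.72, 2.96))))
  nr <- pmin(pmin(config$n_radicals_max, ns),
             pmax(1L, round(stats::rnorm(n, 2.95, 1.04))))
  counts <- lapply(seq_len(n), function(i) {
    if (nr[i] == 1L) return(as.integer(ns[i]))
    cuts <- sort(sample(seq_len(ns[i] - 1L), nr[i] - 1L))
    as.integer(diff(c(0L, cuts, ns[i])))
  })
  dec <- decomposition_table(chars, counts)

  phon <- ifelse(stats::runif(n) < 0.75, 0.5, -0.5)
  pro <- ifelse(phon > 0 & stats::runif(n) < 0.18 / 0.75, 0.5, -0.5)
  norms <- data.frame(
    character = chars,
    phonogram = phon,
    phonetic_radical_order = pro,
    regularity = stats::rnorm(n, 0, 0.85),
    homophone_density = pmax(0, stats::rnorm(n, 0.90, 0.35)),
    n_meanings = 1L + stats::rpois(n, 2.2),
    imageability = stats::rnorm(n, 0, 0.60),
    concreteness = stats::rnorm(n, 0, 0.69),
    frequency = pmin(5, pmax(1.5, stats::rnorm(n, 3.44, 0.68))),
    age_of_acquisition = pmin(15, pmax(6.5, stats::rnorm(n, 8.50, 1.63))),
    n_strokes = as.integer(ns),
    n_radicals = as.integer(nr),
    left_right = ifelse(stats::runif(n) < 0.58, 0.5, -0.5),
    top_down = ifelse(stats::runif(n) < 0.73, 0.5, -0.5),
    word_familiarity = stats::rnorm(n, 0.33, 0.33),
    stringsAsFactors = FALSE)
  z <- scale(as.matrix(norms[lexical_predictors()]))
  z[is.nan(z)] <- 0  # zero-variance predictor (possible at tiny n_items)
  list(decomposition = dec, norms = norms, z = z)
}

#' Simulate a single trial
#'
#' Generates one trial's pen-sample stream with exactly the decomposition's
#' stroke count realized as maximal pressure-positive runs, separated by
#' zero-pressure hover samples, at the configured sampling interval. Mostly
#' useful for inspection and unit tests; [simulate_dataset()] is the batch
#' path.
#'
#' @param stroke_counts Ordered per-radical stroke counts.
#' @param config A [sim_config()].
#' @param seed Optional seed for this trial.
#' @param audio_offset_ms Prompt offset (ms).
#' @param trial_id Trial id stamped on the samples.
#' @return List with `samples`, `truth` (list with the drawn latency, gaps
#'   and durations).
#' @export
simulate_trial <- function(stroke_counts, config, seed = NULL,
                           audio_offset_ms = 2300, trial_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  iv <- config$sampling_interval_ms
  latency <- snap(max(50, config$char_latency_base +
                        rlnorm_mean(1, config$resid_mean, config$resid_sdlog) -
                        config$resid_mean), iv)
  built <- build_streams(list(as.integer(stroke_counts)), latency,
                         shift_rgap = 0, shift_sgap = 0, shift_sdur = 0,
                         circle = FALSE, config = config)
  samples <- built$samples
  samples$trial_id <- trial_id
  samples$t <- samples$t + audio_offset_ms
  st <- built$strokes
  list(samples = samples,
       truth = list(latency = latency,
                    gaps = st$gap[-1],
                    durations = st$duration,
                    stroke_counts = stroke_counts))
}

#' Simulate a complete handwriting-to-dictation experiment
#'
#' Generates every input the analysis pipeline consumes -- pen-sample
#' streams, trial events, rater codes, decomposition table, lexical norms --
#' together with the ground truth that produced them. Character latencies
#' are `base + beta' z(predictors) + item intercept + participant intercept
#' + right-skewed residual`; inter-stroke and radical-boundary gaps and
#' stroke durations are log-normal with their own designed effects; amnesia
#' responses follow a logistic model on the z-scored predictors.
#'
#' @param config A [sim_config()] (its `seed` drives all randomness).
#' @return List of class `sim_dataset`: `samples`, `events`, `raters`,
#'   `decomposition`, `norms`, `ground_truth` (betas, item effects, random
#'   intercepts, per-trial response categories), `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  stim <- simulate_norms(config)
  z <- stim$z
  dec <- stim$decomposition
  nP <- config$n_participants; nI <- config$n_items
  iv <- config$sampling_interval_ms

  shift_char <- as.numeric(z %*% config$beta_char_latency)
  shift_rgap <- as.numeric(z %*% config$beta_radical_latency)
  shift_sgap <- as.numeric(z %*% config$beta_stroke_latency)
  shift_sdur <- as.numeric(z %*% config$beta_stroke_duration)
  p_amnesia <- stats::plogis(config$amnesia_intercept +
                               as.numeric(z %*% config$amnesia_slopes))
  b_item <- stats::rnorm(nI, 0, config$sigma_item)
  u_part <- stats::rnorm(nP, 0, config$sigma_participant)

  n_trials <- nP * nI
  participant <- rep(seq_len(nP), each = nI)
  item <- rep(seq_len(nI), times = nP)
  trial_id <- seq_len(n_trials)

  resp <- ifelse(stats::runif(n_trials) < config$p_dont_know, 2L,
                 ifelse(stats::runif(n_trials) < p_amnesia[item], 1L, 0L))

  lat <- snap(pmax(50, config$char_latency_base + shift_char[item] +
                     b_item[item] + u_part[participant] +
                     rlnorm_mean(n_trials, config$resid_mean,
                                 config$resid_sdlog) - config$resid_mean), iv)

  circle <- resp == 2L
  counts <- dec$radical_stroke_counts[item]
  built <- build_streams(counts, lat,
                         shift_rgap = shift_rgap[item],
                         shift_sgap = shift_sgap[item],
                         shift_sdur = shift_sdur[item],
                         circle = circle, config = config)
  # trial clock: cue 500 ms, dictation audio 1800 ms, writing, spacebar
  # 500 ms after the last ink, then 1500 ms target display + report + ITI
  span <- 2300 + built$last_ink_rel + 500 + 2500
  base <- cumsum(c(0, span[-n_trials]))
  ev_audio_on <- base + 500
  ev_audio_off <- base + 2300
  ev_space <- base + 2300 + built$last_ink_rel + 500
  samples <- built$samples
  samples$t <- samples$t + ev_audio_off[samples$trial_id]
  events <- data.frame(trial_id = trial_id,
                       participant_id = participant,
                       item_number = item,
                       target_char = dec$character[item],
                       audio_onset_ms = ev_audio_on,
                       audio_offset_ms = ev_audio_off,
                       space_press_ms = ev_space,
                       self_report = resp,
                       stringsAsFactors = FALSE)

  # rater codes: expected correctness = (self-report correct); flipped with
  # a small inconsistency probability; revised flags among correct scripts
  expected_correct <- resp == 0L
  raters <- do.call(rbind, lapply(seq_len(config$n_raters), function(r) {
    flip <- stats::runif(n_trials) < config$p_rater_inconsistent
    code <- ifelse(xor(expected_correct, flip), "correct", "incorrect")
    data.frame(trial_id = trial_id, rater_id = r, code = code,
               revised = code == "correct" &
                 stats::runif(n_trials) < config$p_revised,
               stringsAsFactors = FALSE)
  }))

  structure(list(
    samples = samples, events = events, raters = raters,
    decomposition = dec, norms = stim$norms,
    ground_truth = list(
      z = z,
      beta_char_latency = config$beta_char_latency,
      beta_radical_latency = config$beta_radical_latency,
      beta_stroke_latency = config$beta_stroke_latency,
      beta_stroke_duration = config$beta_stroke_duration,
      item_shift_char_latency = shift_char,
      item_intercepts = b_item, participant_intercepts = u_part,
      p_amnesia = p_amnesia, response = resp,
      char_latency_trial = lat),
    config = config), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", x$config$n_participants, "participants x",
      x$config$n_items, "items;", nrow(x$samples), "pen samples\n")
  invisible(x)
}

#' Write a simulated dataset's four input files
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             events = file.path(dir, "events.tsv"),
             decomposition = file.path(dir, "decomposition.tsv"),
             norms = file.path(dir, "norms.tsv"))
  write_pen_samples(sim$samples, paths["samples"])
  write_events(sim$events, paths["events"])
  write_decomposition(sim$decomposition, paths["decomposition"])
  write_lexical_norms(sim$norms, paths["norms"])
  invisible(paths)
}
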