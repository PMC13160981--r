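#' File dialect for pen-sample streams
#'
#' Describes the on-disk layout of a pen-sample file. The default matches the
#' tab-separated layout written by [write_pen_samples()]: UTF-8, header row,
#' columns `t_ms x y pressure trial_id`. Devices or acquisition software that
#' use other column names can be accommodated by remapping `columns`.
#'
#' @param sep Field separator (default tab).
#' @param columns Named character vector mapping the five canonical fields
#'   (`t`, `x`, `y`, `pressure`, `trial`) to the column names used in the file.
#' @return A list of class `pen_dialect`.
#' @export
#' @examples
#' pen_dialect()
#' pen_dialect(columns = c(t = "time", x = "xpos", y = "ypos",
#'                         pressure = "press", trial = "trial"))
pen_dialect <- function(sep = "\t",
                        columns = c(t = "t_ms", x = "x", y = "y",
                                    pressure = "pressure", trial = "trial_id")) {
  needed <- c("t", "x", "y", "pressure", "trial")
  if (!all(needed %in% names(columns)))
    stop("`columns` must name all of: ", paste(needed, collapse = ", "))
  structure(list(sep = sep, columns = columns[needed]), class = "pen_dialect")
}

# internal: classed error helpers so callers/tests can distinguish failures
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("penmetrics_format_error", "error")))
}
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("penmetrics_validation_error", "error")))
}

#' Validate a pen-sample table
#'
#' Checks the typed invariants of a pen-sample stream: timestamps strictly
#' increasing within each trial, non-negative pressure, trial ids >= 1.
#' Errors name the offending (1-based) data row.
#'
#' @param samples Data frame with columns `trial_id`, `t`, `x`, `y`, `pressure`.
#' @return `samples`, invisibly, if valid.
#' @export
validate_pen_samples <- function(samples) {
  req <- c("trial_id", "t", "x", "y", "pressure")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop_format("pen-sample table is missing column(s): ",
                paste(miss, collapse = ", "))
  if (nrow(samples) == 0) return(invisible(samples))
  if (any(bad <- samples$pressure < 0))
    stop_invalid("negative pressure at row ", which(bad)[1])
  if (any(bad <- samples$trial_id < 1))
    stop_invalid("trial_id < 1 at row ", which(bad)[1])
  same_trial <- samples$trial_id[-1] == samples$trial_id[-nrow(samples)]
  nonmono <- same_trial & diff(samples$t) <= 0
  if (any(nonmono))
    stop_invalid("non-monotonic timestamp within trial at row ",
                 which(nonmono)[1] + 1L)
  invisible(samples)
}

#' Read a pen-sample stream
#'
#' Reads a tab-delimited pen-sample file (one row per digitizer sample) and
#' validates it. Samples are returned in file order; timestamps must be
#' strictly increasing within each trial.
#'
#' @param path File path.
#' @param dialect A [pen_dialect()] describing the file layout.
#' @return Data frame with columns `trial_id`, `t`, `x`, `y`, `pressure`
#'   (times in ms, coordinates and pressure in device units).
#' @export
read_pen_samples <- function(path, dialect = pen_dialect()) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  cols <- dialect$columns
  miss <- cols[!cols %in% names(raw)]
  if (length(miss))
    stop_format("pen-sample file is missing column(s): ",
                paste(miss, collapse = ", "))
  samples <- data.frame(
    trial_id = as.integer(raw[[cols[["trial"]]]]),
    t        = as.numeric(raw[[cols[["t"]]]]),
    x        = as.numeric(raw[[cols[["x"]]]]),
    y        = as.numeric(raw[[cols[["y"]]]]),
    pressure = as.numeric(raw[[cols[["pressure"]]]])
  )
  validate_pen_samples(samples)
  samples
}

#' Write a pen-sample stream
#'
#' @param samples Pen-sample data frame (see [read_pen_samples()]).
#' @param path Output path.
#' @param dialect A [pen_dialect()].
#' @return `path`, invisibly.
#' @export
write_pen_samples <- function(samples, path, dialect = pen_dialect()) {
  validate_pen_samples(samples)
  cols <- dialect$columns
  out <- data.frame(samples$t, samples$x, samples$y, samples$pressure,
                    samples$trial_id)
  names(out) <- cols[c("t", "x", "y", "pressure", "trial")]
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-trial event log
#'
#' One row per trial: audio prompt onset/offset, spacebar completion press,
#' the participant's self-report key, and trial identity. Self-report codes
#' follow the response keys: 0 = correct, 1 = character amnesia (knew the
#' character, could not retrieve its form), 2 = don't know.
#'
#' @param path File path (tab-separated, UTF-8, header
#'   `trial_id participant_id item_number target_char audio_onset_ms
#'   audio_offset_ms space_press_ms self_report`).
#' @return Data frame of trial events.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  req <- c("trial_id", "participant_id", "item_number", "target_char",
           "audio_onset_ms", "audio_offset_ms", "space_press_ms", "self_report")
  miss <- setdiff(req, names(ev))
  if (length(miss))
    stop_format("events file is missing column(s): ", paste(miss, collapse = ", "))
  validate_events(ev)
  ev[req]
}

#' @rdname read_events
#' @param events Events data frame.
#' @export
validate_events <- function(events) {
  if (any(bad <- !events$self_report %in% 0:2))
    stop_invalid("self_report outside {0,1,2} at row ", which(bad)[1])
  if (any(bad <- events$audio_offset_ms >= events$space_press_ms))
    stop_invalid("audio_offset_ms >= space_press_ms at row ", which(bad)[1])
  if (anyDuplicated(events$trial_id))
    stop_invalid("duplicated trial_id: ",
                 events$trial_id[duplicated(events$trial_id)][1])
  invisible(events)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check that every sampled trial has an event row
#'
#' Trials present in the sample stream but absent from the event log cannot be
#' analysed (no audio offset to anchor latency); they are reported with a
#' warning and returned so callers can log them.
#'
#' @param samples Pen-sample data frame.
#' @param events Events data frame.
#' @return Integer vector of orphan trial ids (invisibly empty when complete).
#' @export
check_trial_coverage <- function(samples, events) {
  orphans <- sort(setdiff(unique(samples$trial_id), events$trial_id))
  if (length(orphans))
    warning("trial(s) without event row: ", paste(orphans, collapse = ", "),
            call. = FALSE)
  invisible(orphans)
}

#' Read a character decomposition table
#'
#' Maps each character to the ordered per-radical stroke counts used to group
#' detected strokes into radicals. On disk the counts are comma-joined in
#' writing order (e.g. `5,8` for a two-radical, 13-stroke character).
#'
#' @param path File path (tab-separated, header
#'   `character radical_stroke_counts total_strokes`).
#' @return Data frame with columns `character`, `radical_stroke_counts`
#'   (list column of integer vectors), `total_strokes`, `n_radicals`.
#' @export
read_decomposition <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  req <- c("character", "radical_stroke_counts", "total_strokes")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop_format("decomposition file is missing column(s): ",
                paste(miss, collapse = ", "))
  counts <- lapply(strsplit(as.character(raw$radical_stroke_counts), ","),
                   as.integer)
  decomposition_table(raw$character, counts, raw$total_strokes)
}

#' Construct (and validate) a decomposition table in memory
#'
#' @param character Character vector of characters.
#' @param radical_stroke_counts List of integer vectors, strokes per radical
#'   in writing order.
#' @param total_strokes Optional integer vector; when given it is checked
#'   against `sum(radical_stroke_counts)` per character.
#' @return Validated decomposition data frame.
#' @export
decomposition_table <- function(character, radical_stroke_counts,
                                total_strokes = NULL) {
  sums <- vapply(radical_stroke_counts, sum, integer(1))
  if (is.null(total_strokes)) total_strokes <- sums
  bad <- sums != total_strokes |
    vapply(radical_stroke_counts, function(x) any(x < 1L), logical(1))
  if (any(bad))
    stop_invalid("radical stroke counts do not sum to total_strokes for: ",
                 paste(character[bad], collapse = ", "))
  data.frame(character = as.character(character),
             radical_stroke_counts = I(radical_stroke_counts),
             total_strokes = as.integer(total_strokes),
             n_radicals = lengths(radical_stroke_counts),
             stringsAsFactors = FALSE)
}

#' @rdname read_decomposition
#' @param decomposition Decomposition data frame.
#' @export
write_decomposition <- function(decomposition, path) {
  out <- data.frame(
    character = decomposition$character,
    radical_stroke_counts = vapply(decomposition$radical_stroke_counts,
                                   paste, character(1), collapse = ","),
    total_strokes = decomposition$total_strokes)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The fourteen lexical predictors
#'
#' Canonical names, in the conventional reporting order: four phonological
#' (phonogram status, phonetic-radical order, regularity, homophone density),
#' three semantic (number of meanings, imageability, concreteness) and seven
#' orthographic/lexical (frequency, age of acquisition, stroke count, radical
#' count, left-right composition, top-down composition, context-word
#' familiarity). Binary factors are sum-coded as -0.5/+0.5.
#'
#' @return Character vector of 14 column names.
#' @export
lexical_predictors <- function() {
  c("phonogram", "phonetic_radical_order", "regularity", "homophone_density",
    "n_meanings", "imageability", "concreteness", "frequency",
    "age_of_acquisition", "n_strokes", "n_radicals", "left_right",
    "top_down", "word_familiarity")
}

#' Read / write a lexical-norms table
#'
#' One row per character with the 14 predictors of [lexical_predictors()].
#' Sum-coded binary columns must contain only -0.5 and +0.5.
#'
#' @param path File path (tab-separated, UTF-8 header).
#' @return Norms data frame.
#' @export
read_lexical_norms <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  norms <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             fileEncoding = "UTF-8")
  miss <- setdiff(c("character", lexical_predictors()), names(norms))
  if (length(miss))
    stop_format("norms file is missing column(s): ", paste(miss, collapse = ", "))
  validate_lexical_norms(norms)
  norms
}

#' @rdname read_lexical_norms
#' @param norms Norms data frame.
#' @export
validate_lexical_norms <- function(norms) {
  for (col in c("phonogram", "phonetic_radical_order", "left_right", "top_down")) {
    if (!all(norms[[col]] %in% c(-0.5, 0.5)))
      stop_invalid("column ", col, " must be sum-coded -0.5/+0.5")
  }
  if (any(norms$n_strokes < 1) || any(norms$n_radicals < 1))
    stop_invalid("n_strokes and n_radicals must be >= 1")
  invisible(norms)
}

#' @rdname read_lexical_norms
#' @export
write_lexical_norms <- function(norms, path) {
  validate_lexical_norms(norms)
  utils::write.table(norms, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a long-format metric table
#'
#' The long format produced by [extract_metrics()]: one row per unit
#' (character, radical or stroke) per trial. Round-trips exactly.
#'
#' @param path File path.
#' @return Metric data frame.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "", na.strings = "NA",
                         fileEncoding = "UTF-8")
  m$flags[is.na(m$flags)] <- ""
  m
}

#' @rdname read_metrics
#' @param metrics Metric data frame.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a segment-tree sidecar (JSON)
#'
#' Emits the trial -> radical -> stroke grouping with per-stroke sample-index
#' ranges, so segmentations can be inspected in external tools that work with
#' grouped pen-segment trees.
#'
#' @param trees List of `segment_tree` objects (see [segment_trial()]).
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_segment_tree <- function(trees, path) {
  if (inherits(trees, "segment_tree")) trees <- list(trees)
  payload <- lapply(trees, function(tr) {
    st <- tr$strokes
    strokes <- lapply(seq_len(nrow(st)), function(i) list(
      stroke = st$stroke[i],
      radical = if (is.null(tr$radical_of_stroke)) NA_integer_
                else tr$radical_of_stroke[i],
      sample_range = c(st$first_idx[i], st$last_idx[i]),
      onset_t = st$onset_t[i], offset_t = st$offset_t[i]))
    list(trial_id = tr$trial_id, flags = as.list(tr$flags), strokes = strokes)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
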