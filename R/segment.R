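#' Polyline path length
#'
#' Sum of Euclidean distances between consecutive points. A single point has
#' length 0.
#'
#' @param x,y Numeric coordinate vectors of equal length (>= 1 point).
#' @return Non-negative scalar, in the coordinate units of the input.
#' @export
#' @examples
#' path_length(c(0, 3), c(0, 4))   # 5
path_length <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one point")
  if (length(x) == 1L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Detect strokes in one trial's pen-sample run
#'
#' A stroke is a maximal run of consecutive samples with pressure > 0;
#' zero-pressure (pen-in-air) samples separate strokes and contribute to no
#' metric. Onset/offset are the timestamps of the run's first/last sample.
#'
#' @param trial_samples Pen-sample data frame for a single trial, time-sorted.
#' @param min_stroke_samples Minimum samples for a run to count as a stroke;
#'   shorter runs are treated as noise and ignored (default 1 = keep all).
#' @return Data frame with one row per stroke: `stroke` (1-based order),
#'   `onset_t`, `offset_t`, `start_x`, `start_y`, `end_x`, `end_y`, `length`,
#'   `mean_pressure`, `sum_pressure`, `n_samples`, `first_idx`, `last_idx`
#'   (row indices into `trial_samples`). Zero rows when no ink.
#' @export
detect_strokes <- function(trial_samples, min_stroke_samples = 1L) {
  p <- trial_samples$pressure
  n <- length(p)
  empty <- data.frame(stroke = integer(), onset_t = numeric(),
                      offset_t = numeric(), start_x = numeric(),
                      start_y = numeric(), end_x = numeric(), end_y = numeric(),
                      length = numeric(), mean_pressure = numeric(),
                      sum_pressure = numeric(), n_samples = integer(),
                      first_idx = integer(), last_idx = integer())
  if (n == 0L) return(empty)
  r <- rle(p > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_stroke_samples
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  out <- lapply(seq_along(starts), function(k) {
    i <- starts[k]:ends[k]
    data.frame(stroke = k,
               onset_t = trial_samples$t[starts[k]],
               offset_t = trial_samples$t[ends[k]],
               start_x = trial_samples$x[starts[k]],
               start_y = trial_samples$y[starts[k]],
               end_x = trial_samples$x[ends[k]],
               end_y = trial_samples$y[ends[k]],
               length = path_length(trial_samples$x[i], trial_samples$y[i]),
               mean_pressure = mean(trial_samples$pressure[i]),
               sum_pressure = sum(trial_samples$pressure[i]),
               n_samples = length(i),
               first_idx = starts[k], last_idx = ends[k])
  })
  do.call(rbind, out)
}

#' Group detected strokes into radicals
#'
#' Radical membership comes from the decomposition table, never from the ink:
#' radical k receives the next `radical_stroke_counts[k]` strokes in writing
#' order. If the detected stroke count does not match the entry's total, the
#' trial is flagged `decomposition_mismatch` and no radical assignment is made.
#'
#' @param strokes Stroke table from [detect_strokes()].
#' @param radical_stroke_counts Integer vector, strokes per radical in
#'   writing order.
#' @return Integer vector (radical index per stroke), or `NULL` with a
#'   `decomposition_mismatch` attribute-free NULL on count mismatch.
#' @export
group_radicals <- function(strokes, radical_stroke_counts) {
  if (nrow(strokes) != sum(radical_stroke_counts)) return(NULL)
  rep(seq_along(radical_stroke_counts), radical_stroke_counts)
}

#' Segment one trial into its unit tree
#'
#' Runs stroke detection and (when a decomposition entry is supplied) radical
#' grouping, returning a `segment_tree`: the hierarchical unit model of one
#' trial (character -> radicals -> strokes).
#'
#' @inheritParams detect_strokes
#' @param radical_stroke_counts Ordered per-radical stroke counts for the
#'   trial's target character, or `NULL` when no decomposition is available.
#' @param trial_id Trial identifier stored in the tree.
#' @return Object of class `segment_tree`: list with `trial_id`, `strokes`
#'   (stroke table), `radical_of_stroke` (or `NULL`), `flags`, and the
#'   trial's `samples` (kept for rendering, including pen-in-air trace).
#' @export
segment_trial <- function(trial_samples, radical_stroke_counts = NULL,
                          trial_id = trial_samples$trial_id[1],
                          min_stroke_samples = 1L) {
  strokes <- detect_strokes(trial_samples, min_stroke_samples)
  flags <- character()
  if (nrow(strokes) == 0L) flags <- c(flags, "no_ink")
  radical_of_stroke <- NULL
  if (is.null(radical_stroke_counts)) {
    flags <- c(flags, "missing_decomposition")
  } else if (nrow(strokes) > 0L) {
    radical_of_stroke <- group_radicals(strokes, radical_stroke_counts)
    if (is.null(radical_of_stroke)) flags <- c(flags, "decomposition_mismatch")
  }
  structure(list(trial_id = trial_id, strokes = strokes,
                 radical_of_stroke = radical_of_stroke, flags = flags,
                 samples = trial_samples),
            class = "segment_tree")
}

#' @export
print.segment_tree <- function(x, ...) {
  cat("<segment_tree> trial", x$trial_id, "-", nrow(x$strokes), "stroke(s)")
  if (!is.null(x$radical_of_stroke))
    cat(",", max(x$radical_of_stroke), "radical(s)")
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# one empty long-format metric row (internal)
metric_row <- function(trial_id, level, unit_index = 1L) {
  data.frame(trial_id = trial_id, level = level, unit_index = unit_index,
             latency_ms = NA_real_, duration_ms = NA_real_,
             length = NA_real_, pressure = NA_real_, distance = NA_real_,
             flags = "", stringsAsFactors = FALSE)
}

#' Character-level metrics for one trial
#'
#' Latency is measured from the offset of the auditory stimulus to the pen
#' first touching the tablet; duration from first touch to the last non-zero
#' pressure sample; trace length is the sum of the stroke path lengths; mean
#' pressure averages over all on-paper (ink) samples. Pen-in-air samples
#' contribute to nothing.
#'
#' @param tree A [segment_trial()] result.
#' @param audio_offset_ms Offset time of the dictation prompt (ms).
#' @return One-row metric data frame (`level == "character"`). If the trial
#'   has no ink the metrics are `NA` and the row is flagged `no_ink`.
#' @export
character_metrics <- function(tree, audio_offset_ms) {
  st <- tree$strokes
  row <- metric_row(tree$trial_id, "character")
  if (nrow(st) == 0L) {
    row$flags <- paste(unique(c(tree$flags, "no_ink")), collapse = ";")
    return(row)
  }
  row$latency_ms <- st$onset_t[1] - audio_offset_ms
  row$duration_ms <- st$offset_t[nrow(st)] - st$onset_t[1]
  row$length <- sum(st$length)
  row$pressure <- sum(st$sum_pressure) / sum(st$n_samples)
  row$flags <- paste(tree$flags, collapse = ";")
  row
}

#' Radical-level metrics for one trial
#'
#' A radical's onset/offset are the onset of its first and offset of its last
#' stroke (radicals have no pen events of their own). Latency and distance
#' are inter-unit intervals -- the gap and straight-line jump from the
#' previous radical -- and are therefore undefined (`NA`) for the first
#' radical.
#'
#' @param tree A [segment_trial()] result with a radical assignment.
#' @return Metric data frame, one row per radical (`level == "radical"`);
#'   zero rows when no radical grouping is available.
#' @export
radical_metrics <- function(tree) {
  rad <- tree$radical_of_stroke
  if (is.null(rad) || nrow(tree$strokes) == 0L)
    return(metric_row(tree$trial_id, "radical")[0, ])
  st <- tree$strokes
  out <- lapply(sort(unique(rad)), function(r) {
    m <- st[rad == r, ]
    row <- metric_row(tree$trial_id, "radical", r)
    row$duration_ms <- m$offset_t[nrow(m)] - m$onset_t[1]
    row$length <- sum(m$length)
    row$pressure <- sum(m$sum_pressure) / sum(m$n_samples)
    if (r > 1L) {
      prev <- st[rad == r - 1L, ]
      row$latency_ms <- m$onset_t[1] - prev$offset_t[nrow(prev)]
      row$distance <- sqrt((m$start_x[1] - prev$end_x[nrow(prev)])^2 +
                           (m$start_y[1] - prev$end_y[nrow(prev)])^2)
    }
    row
  })
  do.call(rbind, out)
}

#' Stroke-level metrics for one trial
#'
#' Per stroke: latency (gap from the previous stroke's offset; `NA` for the
#' first stroke), duration (last minus first sample timestamp), path length,
#' mean pressure, and straight-line distance from the previous stroke's end
#' point to this stroke's start point (`NA` for the first stroke).
#'
#' @param tree A [segment_trial()] result.
#' @return Metric data frame, one row per stroke (`level == "stroke"`).
#' @export
stroke_metrics <- function(tree) {
  st <- tree$strokes
  if (nrow(st) == 0L) return(metric_row(tree$trial_id, "stroke")[0, ])
  n <- nrow(st)
  out <- metric_row(tree$trial_id, "stroke", seq_len(n))
  out$duration_ms <- st$offset_t - st$onset_t
  out$length <- st$length
  out$pressure <- st$mean_pressure
  if (n > 1L) {
    out$latency_ms[-1] <- st$onset_t[-1] - st$offset_t[-n]
    out$distance[-1] <- sqrt((st$start_x[-1] - st$end_x[-n])^2 +
                             (st$start_y[-1] - st$end_y[-n])^2)
  }
  out
}
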