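#' Extract all handwriting metrics from a dataset
#'
#' The batch path of the pipeline: segments every trial's pen-sample run into
#' strokes, groups strokes into radicals via the decomposition table, and
#' returns the full long-format metric table at all three unit levels. The
#' computation is vectorized across trials and agrees exactly with the
#' per-trial functions ([character_metrics()], [radical_metrics()],
#' [stroke_metrics()]).
#'
#' @param samples Pen-sample data frame (all trials).
#' @param events Trial-event data frame; every trial to be analysed needs an
#'   event row (it anchors character latency to the audio offset). Trials in
#'   `samples` without an event row are dropped with a warning.
#' @param decomposition Optional decomposition table
#'   (see [read_decomposition()]). Trials whose target character is missing
#'   from it get no radical-level rows and are flagged
#'   `missing_decomposition`; trials whose detected stroke count disagrees
#'   with the entry are flagged `decomposition_mismatch`.
#' @param min_stroke_samples Minimum samples per stroke (see
#'   [detect_strokes()]).
#' @return Long-format data frame, one row per unit per trial, columns
#'   `participant_id`, `item_number`, `target_char`, `trial_id`, `level`
#'   (`"character"`, `"radical"` or `"stroke"`), `unit_index`, `latency_ms`,
#'   `duration_ms`, `length`, `pressure`, `distance`, `flags`. Latency and
#'   distance are `NA` for first radicals/strokes (no previous unit) and
#'   distance is `NA` at the character level.
#' @export
extract_metrics <- function(samples, events, decomposition = NULL,
                            min_stroke_samples = 1L) {
  check_trial_coverage(samples, events)
  samples <- samples[samples$trial_id %in% events$trial_id, , drop = FALSE]
  o <- order(samples$trial_id, samples$t)
  s <- samples[o, , drop = FALSE]
  n <- nrow(s)

  st <- if (n > 0L) {
    ink <- s$pressure > 0
    new_trial <- c(TRUE, s$trial_id[-1] != s$trial_id[-n])
    run_start <- ink & (new_trial | c(TRUE, !ink[-n]))
    run_id <- cumsum(run_start)
    run_id[!ink] <- NA_integer_
    build_stroke_table(s, ink, run_id, min_stroke_samples)
  } else {
    detect_strokes(samples[0, ])
  }

  ev_at <- match(st$trial_id, events$trial_id)
  st$target_char <- events$target_char[ev_at]

  char_rows <- character_rows(st, events)
  stroke_rows <- stroke_rows(st)
  radical_rows <- radical_rows_grouped(st, decomposition)

  # trial-level flags live on the character row
  flags <- rep("", nrow(char_rows))
  if (!is.null(decomposition)) {
    dmatch <- match(char_rows$target_char, decomposition$character)
    has_ink <- char_rows$flags != "no_ink"
    nstrokes <- as.integer(table(factor(st$trial_id,
                                        levels = char_rows$trial_id)))
    mism <- has_ink & !is.na(dmatch) &
      nstrokes != decomposition$total_strokes[dmatch]
    missing_dec <- is.na(dmatch)
    flags[mism] <- "decomposition_mismatch"
    flags[missing_dec] <- "missing_decomposition"
  } else {
    flags[] <- "missing_decomposition"
  }
  char_rows$flags <- ifelse(char_rows$flags == "", flags,
                            ifelse(flags == "", char_rows$flags,
                                   paste(char_rows$flags, flags, sep = ";")))

  out <- rbind(char_rows, radical_rows, stroke_rows)
  ev_at <- match(out$trial_id, events$trial_id)
  out$participant_id <- events$participant_id[ev_at]
  out$item_number <- events$item_number[ev_at]
  out$target_char <- events$target_char[ev_at]
  out <- out[order(out$trial_id, match(out$level,
                                       c("character", "radical", "stroke")),
                   out$unit_index), , drop = FALSE]
  out <- out[c("participant_id", "item_number", "target_char", "trial_id",
               "level", "unit_index", "latency_ms", "duration_ms", "length",
               "pressure", "distance", "flags")]
  rownames(out) <- NULL
  out
}

# vectorized stroke table for the whole dataset (internal)
build_stroke_table <- function(s, ink, run_id, min_stroke_samples) {
  idx <- which(ink)
  if (length(idx) == 0L) return(cbind(detect_strokes(s[0, ]), trial_id = integer()))
  rid <- run_id[idx]
  sizes <- tabulate(rid)
  keep_run <- which(sizes >= min_stroke_samples)
  if (min_stroke_samples > 1L) {
    sel <- rid %in% keep_run
    idx <- idx[sel]; rid <- rid[sel]
    if (length(idx) == 0L) return(cbind(detect_strokes(s[0, ]), trial_id = integer()))
  }
  firsts <- idx[!duplicated(rid)]
  lasts  <- idx[!duplicated(rid, fromLast = TRUE)]
  urid <- rid[!duplicated(rid)]

  # per-run path length: segments between consecutive ink samples of one run
  n <- nrow(s)
  both_ink <- ink[-n] & ink[-1]
  same_run <- both_ink
  same_run[both_ink] <- run_id[-n][both_ink] == run_id[-1][both_ink]
  if (min_stroke_samples > 1L)
    same_run <- same_run & c(run_id[-n] %in% keep_run)
  segs <- which(same_run)
  d <- sqrt((s$x[segs + 1L] - s$x[segs])^2 + (s$y[segs + 1L] - s$y[segs])^2)
  len <- numeric(max(urid))
  if (length(segs)) {
    agg <- rowsum(d, group = run_id[segs], reorder = FALSE)
    len[as.integer(rownames(agg))] <- agg[, 1]
  }
  sum_p <- numeric(max(urid))
  aggp <- rowsum(s$pressure[idx], group = rid, reorder = FALSE)
  sum_p[as.integer(rownames(aggp))] <- aggp[, 1]
  nsamp <- tabulate(rid)[urid]

  trial <- s$trial_id[firsts]
  k <- stats::ave(seq_along(firsts), trial, FUN = seq_along)
  data.frame(stroke = k,
             onset_t = s$t[firsts], offset_t = s$t[lasts],
             start_x = s$x[firsts], start_y = s$y[firsts],
             end_x = s$x[lasts], end_y = s$y[lasts],
             length = len[urid],
             mean_pressure = sum_p[urid] / nsamp,
             sum_pressure = sum_p[urid],
             n_samples = nsamp,
             first_idx = firsts, last_idx = lasts,
             trial_id = trial)
}

# character-level rows for every trial in events (internal)
character_rows <- function(st, events) {
  trials <- events$trial_id
  first_of <- match(trials, st$trial_id)
  # last stroke row of each trial
  last_of <- nrow(st) + 1L - match(trials, rev(st$trial_id))
  out <- data.frame(trial_id = trials, level = "character", unit_index = 1L,
                    latency_ms = NA_real_, duration_ms = NA_real_,
                    length = NA_real_, pressure = NA_real_,
                    distance = NA_real_, flags = "",
                    stringsAsFactors = FALSE)
  has <- !is.na(first_of)
  out$latency_ms[has] <- st$onset_t[first_of[has]] - events$audio_offset_ms[has]
  out$duration_ms[has] <- st$offset_t[last_of[has]] - st$onset_t[first_of[has]]
  if (any(has)) {
    lsum <- rowsum(cbind(st$length, st$sum_pressure, st$n_samples),
                   group = st$trial_id, reorder = FALSE)
    at <- match(trials[has], as.integer(rownames(lsum)))
    out$length[has] <- lsum[at, 1]
    out$pressure[has] <- lsum[at, 2] / lsum[at, 3]
  }
  out$flags[!has] <- "no_ink"
  out$target_char <- events$target_char
  out$participant_id <- events$participant_id
  out$item_number <- events$item_number
  out
}

# stroke-level rows (internal)
stroke_rows <- function(st) {
  if (nrow(st) == 0L)
    return(annotate_empty(st))
  n <- nrow(st)
  same_trial <- c(FALSE, st$trial_id[-1] == st$trial_id[-n])
  lat <- dist <- rep(NA_real_, n)
  lat[same_trial] <- st$onset_t[same_trial] - st$offset_t[which(same_trial) - 1L]
  prev <- which(same_trial) - 1L
  dist[same_trial] <- sqrt((st$start_x[same_trial] - st$end_x[prev])^2 +
                           (st$start_y[same_trial] - st$end_y[prev])^2)
  data.frame(trial_id = st$trial_id, level = "stroke", unit_index = st$stroke,
             latency_ms = lat, duration_ms = st$offset_t - st$onset_t,
             length = st$length, pressure = st$mean_pressure,
             distance = dist, flags = "", target_char = st$target_char,
             participant_id = NA_integer_, item_number = NA_integer_,
             stringsAsFactors = FALSE)
}

annotate_empty <- function(st) {
  data.frame(trial_id = integer(), level = character(), unit_index = integer(),
             latency_ms = numeric(), duration_ms = numeric(),
             length = numeric(), pressure = numeric(), distance = numeric(),
             flags = character(), target_char = character(),
             participant_id = integer(), item_number = integer(),
             stringsAsFactors = FALSE)
}

# radical-level rows via the decomposition table (internal)
radical_rows_grouped <- function(st, decomposition) {
  if (is.null(decomposition) || nrow(st) == 0L) return(annotate_empty(st))
  dmatch <- match(st$target_char, decomposition$character)
  tot <- decomposition$total_strokes[dmatch]
  ns <- stats::ave(st$stroke, st$trial_id, FUN = max)
  ok <- !is.na(tot) & ns == tot
  if (!any(ok)) return(annotate_empty(st))
  sub <- st[ok, , drop = FALSE]
  # radical index pattern per trial, replicated in trial order
  first_in_trial <- !duplicated(sub$trial_id)
  keys <- dmatch[ok][first_in_trial]
  patterns <- lapply(decomposition$radical_stroke_counts,
                     function(cc) rep(seq_along(cc), cc))
  rad <- unlist(patterns[keys], use.names = FALSE)

  m <- nrow(sub)
  new_grp <- c(TRUE, sub$trial_id[-1] != sub$trial_id[-m] | rad[-1] != rad[-m])
  gid <- cumsum(new_grp)
  gfirst <- which(new_grp)
  glast <- c(gfirst[-1] - 1L, m)
  sums <- rowsum(cbind(sub$length, sub$sum_pressure, sub$n_samples),
                 group = gid, reorder = FALSE)
  g <- length(gfirst)
  trial <- sub$trial_id[gfirst]
  same_trial <- c(FALSE, trial[-1] == trial[-g])
  lat <- dist <- rep(NA_real_, g)
  prev <- which(same_trial) - 1L
  lat[same_trial] <- sub$onset_t[gfirst[same_trial]] - sub$offset_t[glast[prev]]
  dist[same_trial] <- sqrt(
    (sub$start_x[gfirst[same_trial]] - sub$end_x[glast[prev]])^2 +
    (sub$start_y[gfirst[same_trial]] - sub$end_y[glast[prev]])^2)
  data.frame(trial_id = trial, level = "radical", unit_index = rad[gfirst],
             latency_ms = lat,
             duration_ms = sub$offset_t[glast] - sub$onset_t[gfirst],
             length = sums[, 1], pressure = sums[, 2] / sums[, 3],
             distance = dist, flags = "",
             target_char = sub$target_char[gfirst],
             participant_id = NA_integer_, item_number = NA_integer_,
             stringsAsFactors = FALSE)
}
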