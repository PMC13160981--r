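#' Code responses against rater judgements
#'
#' Combines participants' self-reports with manual penscript codes. Raters
#' mark a penscript `correct` if they recognize it as the target character,
#' `incorrect` otherwise, and flag revised penscripts (false starts, crossed
#' characters or radicals). With several raters per trial the majority code
#' wins; even ties break toward `incorrect` (conservative). A trial is
#' `consistent` when the self-report and the rater code agree, i.e. a
#' "correct" self-report pairs with a rater-judged correct penscript and any
#' other self-report with an incorrect one.
#'
#' @param events Trial events (with `self_report` 0/1/2).
#' @param rater_table Data frame with columns `trial_id`, `code`
#'   (`"correct"`/`"incorrect"`), `revised` (logical), optionally `rater_id`
#'   when trials carry several codes.
#' @return List of class `penscript_codes`: `codes` (per-trial data frame
#'   with `rater_code`, `revised`, `self_report`, `consistent`),
#'   `consistency_rate` (fraction of coded trials consistent), and
#'   `uncoded_trials` (trial ids without any rater code, excluded from the
#'   rate).
#' @export
code_responses <- function(events, rater_table) {
  if (!all(rater_table$code %in% c("correct", "incorrect")))
    stop_invalid("rater codes must be 'correct' or 'incorrect'")
  n_cor <- tapply(rater_table$code == "correct", rater_table$trial_id, sum)
  n_tot <- tapply(rater_table$code == "correct", rater_table$trial_id, length)
  maj <- ifelse(n_cor > n_tot / 2, "correct", "incorrect")  # ties -> incorrect
  rev <- tapply(rater_table$revised, rater_table$trial_id, any)
  at <- match(events$trial_id, names(maj))
  codes <- data.frame(trial_id = events$trial_id,
                      rater_code = unname(maj[at]),
                      revised = unname(rev[at]),
                      self_report = events$self_report,
                      stringsAsFactors = FALSE)
  codes$consistent <- (codes$self_report == 0L) == (codes$rater_code == "correct")
  uncoded <- events$trial_id[is.na(at)]
  rate <- mean(codes$consistent[!is.na(codes$rater_code)])
  structure(list(codes = codes, consistency_rate = rate,
                 uncoded_trials = uncoded),
            class = "penscript_codes")
}

#' @export
print.penscript_codes <- function(x, ...) {
  cat("<penscript_codes>", nrow(x$codes), "trials;",
      sprintf("self-report/rater consistency %.2f%%", 100 * x$consistency_rate),
      "\n")
  if (length(x$uncoded_trials))
    cat("  uncoded trials:", length(x$uncoded_trials), "\n")
  invisible(x)
}

#' Trials retained for metric analyses
#'
#' Incorrect and revised penscripts are excluded from the analyses of writing
#' latency, duration, length and pen pressure; only rater-judged correct,
#' unrevised trials are retained. (Amnesia rates are computed from
#' self-reports before this filter.)
#'
#' @param codes A [code_responses()] result (or its `codes` data frame).
#' @return Integer vector of retained trial ids.
#' @export
filter_analysis_trials <- function(codes) {
  if (inherits(codes, "penscript_codes")) codes <- codes$codes
  keep <- !is.na(codes$rater_code) & codes$rater_code == "correct" &
    !is.na(codes$revised) & !codes$revised
  codes$trial_id[keep]
}

#' Metric exclusion thresholds
#'
#' Defaults follow the standard outlier rules for this task: character-level
#' writing latencies longer than 10 s and durations shorter than 1 s or
#' longer than 10 s are removed; at the radical and stroke levels, latencies
#' and durations longer than 2 s are removed. All bounds are exclusive
#' (a value exactly at a bound is kept).
#'
#' @param char_lat_max,char_dur_min,char_dur_max,sub_lat_max,sub_dur_max
#'   Thresholds in ms.
#' @return A named list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(char_lat_max = 10000, char_dur_min = 1000,
                            char_dur_max = 10000, sub_lat_max = 2000,
                            sub_dur_max = 2000) {
  structure(list(char_lat_max = char_lat_max, char_dur_min = char_dur_min,
                 char_dur_max = char_dur_max, sub_lat_max = sub_lat_max,
                 sub_dur_max = sub_dur_max),
            class = "exclusion_rules")
}

#' Apply metric-level outlier exclusions
#'
#' Removal is per metric, not per unit: an excluded latency does not remove
#' the same unit's duration (the two metrics can show different exclusion
#' rates). Excluded cells are set to `NA`; all other columns are untouched,
#' so the filter is idempotent.
#'
#' @param records Long-format metric table from [extract_metrics()].
#' @param rules An [exclusion_rules()] list.
#' @return List of class `exclusion_result`: `records` (filtered table) and
#'   `report` (per level x metric counts and percentages removed).
#' @export
apply_metric_exclusions <- function(records, rules = exclusion_rules()) {
  lv <- records$level
  if (!all(lv %in% c("character", "radical", "stroke")))
    stop_invalid("unknown level label: ",
                 paste(setdiff(unique(lv), c("character", "radical", "stroke")),
                       collapse = ", "))
  is_char <- lv == "character"
  is_sub <- !is_char
  lat <- records$latency_ms
  dur <- records$duration_ms
  rm_lat <- (is_char & !is.na(lat) & lat > rules$char_lat_max) |
            (is_sub  & !is.na(lat) & lat > rules$sub_lat_max)
  rm_dur <- (is_char & !is.na(dur) &
               (dur < rules$char_dur_min | dur > rules$char_dur_max)) |
            (is_sub  & !is.na(dur) & dur > rules$sub_dur_max)
  out <- records
  out$latency_ms[rm_lat] <- NA_real_
  out$duration_ms[rm_dur] <- NA_real_

  lv_f <- factor(lv, levels = c("character", "radical", "stroke"))
  report <- rbind(
    exclusion_report_rows(lv_f, !is.na(lat), rm_lat, "latency"),
    exclusion_report_rows(lv_f, !is.na(dur), rm_dur, "duration"))
  report$rule <- c(
    sprintf("latency > %g ms", c(rules$char_lat_max, rules$sub_lat_max,
                                 rules$sub_lat_max)),
    sprintf("duration < %g or > %g ms", rules$char_dur_min, rules$char_dur_max),
    sprintf("duration > %g ms", c(rules$sub_dur_max, rules$sub_dur_max)))
  structure(list(records = out, report = report), class = "exclusion_result")
}

exclusion_report_rows <- function(lv_f, present, removed, metric) {
  n_before <- as.integer(tapply(present, lv_f, sum, default = 0L))
  n_removed <- as.integer(tapply(removed, lv_f, sum, default = 0L))
  data.frame(level = levels(lv_f), metric = metric,
             n_before = n_before, n_removed = n_removed,
             percent_removed = ifelse(n_before > 0,
                                      100 * n_removed / n_before, NA_real_),
             stringsAsFactors = FALSE)
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat("<exclusion_result>\n")
  rep <- x$report
  rep$percent_removed <- sprintf("%.2f%%", rep$percent_removed)
  print(rep, row.names = FALSE)
  invisible(x)
}
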