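#' Aggregate trial-level metrics to item-level norms
#'
#' Collapses the long-format metric table to one row per unique character.
#' Radical- and stroke-level metrics are first averaged within each trial
#' (across that trial's units, skipping the undefined first-unit latency and
#' distance), then averaged across participants; character-level metrics are
#' averaged across participants directly. This keeps the character as the
#' unit of analysis at all three orthographic levels. Amnesia rate is the
#' proportion of "character amnesia" self-reports, computed from the raw
#' events *before* metric exclusions (amnesia trials have no valid character
#' to time).
#'
#' @param records Metric table, normally after [apply_metric_exclusions()]
#'   and restricted to trials from [filter_analysis_trials()] (restriction
#'   can be done here via `retained`).
#' @param events Trial events (used for the amnesia rate; optional).
#' @param retained Optional trial ids to keep for the metric means (amnesia
#'   rates always use all eligible trials).
#' @param amnesia_denominator `"non_dont_know"` (default: trials whose
#'   self-report is not "don't know") or `"all"` (all trials of the item).
#' @return Data frame, one row per `target_char`: `n_trials`, `amnesia_rate`,
#'   and `<level>_<metric>` means (`character_latency` ... `stroke_distance`),
#'   in ms / device units. Items with no retained trials for a metric get
#'   `NA`; they are listed in the `"log"` attribute.
#' @export
aggregate_items <- function(records, events = NULL, retained = NULL,
                            amnesia_denominator = c("non_dont_know", "all")) {
  amnesia_denominator <- match.arg(amnesia_denominator)
  metric_records <- records
  if (!is.null(retained))
    metric_records <- metric_records[metric_records$trial_id %in% retained, ,
                                     drop = FALSE]

  chars <- sort(unique(records$target_char))
  out <- data.frame(target_char = chars, stringsAsFactors = FALSE)

  ch <- metric_records[metric_records$level == "character", , drop = FALSE]
  out$n_trials <- as.integer(table(factor(ch$target_char, levels = chars)))

  if (!is.null(events)) {
    elig <- if (amnesia_denominator == "non_dont_know")
      events[events$self_report != 2L, , drop = FALSE] else events
    num <- tapply(elig$self_report == 1L, factor(elig$target_char, levels = chars),
                  mean)
    out$amnesia_rate <- as.numeric(num)
  }

  item_mean <- function(df, col) {
    as.numeric(tapply(df[[col]], factor(df$target_char, levels = chars),
                      mean, na.rm = TRUE))
  }
  out$character_latency  <- item_mean(ch, "latency_ms")
  out$character_duration <- item_mean(ch, "duration_ms")
  out$character_length   <- item_mean(ch, "length")
  out$character_pressure <- item_mean(ch, "pressure")

  for (level in c("radical", "stroke")) {
    sub <- metric_records[metric_records$level == level, , drop = FALSE]
    for (col in c("latency_ms", "duration_ms", "length", "pressure",
                  "distance")) {
      # mean within trial (across units), then across trials
      tr <- tapply(sub[[col]], sub$trial_id, mean, na.rm = TRUE)
      tr_char <- sub$target_char[match(names(tr), sub$trial_id)]
      v <- tapply(as.numeric(tr), factor(tr_char, levels = chars),
                  mean, na.rm = TRUE)
      out[[paste0(level, "_", sub("_ms$", "", col))]] <- as.numeric(v)
    }
  }
  out[] <- lapply(out, function(v) { v[is.nan(v)] <- NA; v })

  missing_cells <- which(is.na(out[setdiff(names(out),
                                           c("target_char", "amnesia_rate"))]),
                         arr.ind = TRUE)
  if (nrow(missing_cells))
    attr(out, "log") <- paste0(out$target_char[missing_cells[, 1]], ":",
                               setdiff(names(out),
                                       c("target_char", "amnesia_rate"))[
                                         missing_cells[, 2]])
  out
}

#' Spearman-Brown prophecy correction
#'
#' Steps a half-test correlation up to full-test length: `2r / (1 + r)`.
#' Monotone increasing on (-1, 1], fixing 0 and 1.
#'
#' @param r_half Correlation between two test halves (> -1).
#' @return Corrected reliability.
#' @export
#' @examples
#' spearman_brown(0.9)  # 0.947...
spearman_brown <- function(r_half) {
  if (any(r_half <= -1) || any(r_half > 1))
    stop("r_half must lie in (-1, 1]")
  2 * r_half / (1 + r_half)
}

#' Split-half reliability of item-level estimates
#'
#' Participants are randomly divided into two equal groups; the item-level
#' measure is computed separately for each half; the Pearson correlation of
#' the two item vectors is corrected with the Spearman-Brown prophecy
#' formula. With an odd number of participants one is dropped at random
#' (reported in the result).
#'
#' @param trial_table Data frame with one row per trial:
#'   columns `participant_id`, `target_char`, and the measure.
#' @param measure Name of the measure column (e.g. a trial latency, or a 0/1
#'   amnesia indicator whose item mean is the amnesia rate).
#' @param seed Optional integer; the split is deterministic under a fixed
#'   seed.
#' @return List of class `reliability_result`: `r_half`, `r_corrected`,
#'   `n_items`, `n_per_half`, `dropped_participant`.
#' @export
split_half_reliability <- function(trial_table, measure, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(trial_table$participant_id)
  if (length(ids) < 2) stop("need at least 2 participants")
  dropped <- NULL
  if (length(ids) %% 2L == 1L) {
    dropped <- sample(ids, 1L)
    ids <- setdiff(ids, dropped)
  }
  half1 <- sample(ids, length(ids) / 2L)
  item_means <- function(sub) {
    tapply(sub[[measure]], sub$target_char, mean, na.rm = TRUE)
  }
  m1 <- item_means(trial_table[trial_table$participant_id %in% half1, ])
  m2 <- item_means(trial_table[!trial_table$participant_id %in% c(half1, dropped), ])
  common <- intersect(names(m1), names(m2))
  v1 <- m1[common]; v2 <- m2[common]
  ok <- is.finite(v1) & is.finite(v2)
  if (mean(ok) < 0.5)
    stop("measure '", measure, "' missing for more than half the items")
  r <- stats::cor(v1[ok], v2[ok])
  structure(list(r_half = r, r_corrected = spearman_brown(r),
                 n_items = sum(ok), n_per_half = length(half1),
                 dropped_participant = dropped),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(paste0("Split-half reliability: r_half = %.3f, ",
                     "Spearman-Brown corrected r = %.3f (N = %d items, ",
                     "%d participants per half)\n"),
              x$r_half, x$r_corrected, x$n_items, x$n_per_half))
  invisible(x)
}

#' Inter-rater intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC with its
#' F-based 95% confidence interval (McGraw & Wong's case 2A): appropriate
#' when every item is coded by the same set of interchangeable raters drawn
#' from a larger pool. Computed from the two-way ANOVA mean squares of the
#' item x rater table.
#'
#' @param ratings Numeric matrix, items in rows, raters in columns
#'   (>= 2 raters, >= 2 items; binary codes may be given as 0/1).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List of class `icc_result`: `icc`, `ci` (length-2 vector),
#'   `n_items`, `n_raters`.
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 items and >= 2 raters")
  if (anyNA(ratings)) stop("ratings must be complete")
  if (stats::var(as.vector(ratings)) == 0)
    stop("ICC undefined: ratings are constant")
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  grand <- mean(ratings)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  F1 <- stats::qf(1 - alpha / 2, n - 1, v)
  F2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - F1 * MSE) /
    (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (F2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
  structure(list(icc = icc, ci = c(lower = lower, upper = upper),
                 n_items = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f, 95%% CI [%.3f, %.3f] (%d items x %d raters)\n",
              x$icc, x$ci[1], x$ci[2], x$n_items, x$n_raters))
  invisible(x)
}

#' Correlation matrix with significance stars
#'
#' Pairwise Pearson correlations over complete cases; for a pair of binary
#' sum-coded (-0.5/+0.5) variables the Pearson coefficient equals the phi
#' coefficient. Stars mark two-sided significance at .05 / .01 / .001.
#'
#' @param data Data frame of numeric variables.
#' @return List of class `cor_table`: `r` (correlation matrix), `p`
#'   (p-value matrix), `stars` (character matrix). Zero-variance columns give
#'   `NA` entries and are listed in `zero_variance`.
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, logical(1))
  data <- data[num]
  p <- ncol(data)
  zv <- names(data)[vapply(data, function(v) stats::var(v, na.rm = TRUE) == 0,
                           logical(1))]
  r <- suppressWarnings(stats::cor(data, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(as.matrix(data)))
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(abs(tstat), pmax(n - 2, 1), lower.tail = FALSE)
  diag(pv) <- NA
  stars <- matrix("", p, p, dimnames = dimnames(r))
  stars[!is.na(pv) & pv < .05] <- "*"
  stars[!is.na(pv) & pv < .01] <- "**"
  stars[!is.na(pv) & pv < .001] <- "***"
  structure(list(r = r, p = pv, stars = stars, zero_variance = zv),
            class = "cor_table")
}

#' @export
print.cor_table <- function(x, digits = 2, ...) {
  m <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
              nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  m[upper.tri(m)] <- ""
  print(m, quote = FALSE)
  if (length(x$zero_variance))
    cat("zero-variance column(s):", paste(x$zero_variance, collapse = ", "), "\n")
  invisible(x)
}

#' Stepwise variance-inflation-factor screening
#'
#' Computes the VIF of every predictor (1 / (1 - R^2) from the regression of
#' that predictor on all the others) and iteratively removes the predictor
#' with the highest VIF until all remaining VIFs fall below the threshold.
#' Exactly collinear predictors (infinite VIF) are dropped first with a
#' warning; ties break alphabetically.
#'
#' @param predictors Data frame of numeric predictors (n rows > p columns).
#' @param threshold VIF threshold (default 5; a predictor is dropped while
#'   any VIF >= threshold).
#' @return List of class `collinearity_report`: `vif` (final VIFs of retained
#'   predictors), `retained`, `dropped` (in drop order), `steps` (per-step
#'   VIF tables), `threshold`.
#' @export
vif_screen <- function(predictors, threshold = 5) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  if (nrow(X) <= ncol(X)) stop("need more observations than predictors")
  vifs_of <- function(X) {
    vapply(names(X), function(v) {
      fit <- stats::lm(X[[v]] ~ ., data = X[setdiff(names(X), v)])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  steps <- list(); dropped <- character()
  repeat {
    v <- vifs_of(X)
    steps[[length(steps) + 1L]] <- v
    if (all(v < threshold)) break
    worst <- sort(names(v)[v == max(v)])[1]  # ties: alphabetical
    if (is.infinite(max(v)))
      warning("perfectly collinear predictor dropped: ", worst, call. = FALSE)
    dropped <- c(dropped, worst)
    X <- X[setdiff(names(X), worst)]
    if (ncol(X) == 1L) {  # a lone survivor is trivially uninflated
      steps[[length(steps) + 1L]] <- stats::setNames(1, names(X))
      break
    }
  }
  structure(list(vif = steps[[length(steps)]], retained = names(X),
                 dropped = dropped, steps = steps, threshold = threshold),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("<collinearity_report> threshold", x$threshold, "\n")
  print(round(x$vif, 3))
  if (length(x$dropped)) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `q` over one family of
#' p-values (conventionally, the lexical-predictor terms of one regression
#' model).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param q FDR level (default .05).
#' @return Logical vector of flags; the BH-adjusted p-values are attached as
#'   attribute `"p_adjusted"`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  structure(!is.na(adj) & adj <= q, p_adjusted = adj)
}
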