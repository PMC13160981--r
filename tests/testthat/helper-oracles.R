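# Brute-force reference implementations, written as plain loops and kept
# independent of the package's code paths. They define the expected values
# for the segmentation and statistics tests.

# run-length scan: list of c(first, last) sample-index pairs with pressure > 0
oracle_stroke_runs <- function(pressure) {
  runs <- list()
  i <- 1L
  n <- length(pressure)
  while (i <= n) {
    if (pressure[i] > 0) {
      j <- i
      while (j < n && pressure[j + 1L] > 0) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

oracle_path_length <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1L))
    total <- total + sqrt((x[i + 1L] - x[i])^2 + (y[i + 1L] - y[i])^2)
  total
}

# full Table-style metric computation for one trial, by loops
oracle_trial_metrics <- function(samples, audio_offset, counts = NULL) {
  runs <- oracle_stroke_runs(samples$pressure)
  S <- length(runs)
  stroke <- data.frame(latency_ms = rep(NA_real_, S),
                       duration_ms = rep(NA_real_, S),
                       length = rep(NA_real_, S),
                       pressure = rep(NA_real_, S),
                       distance = rep(NA_real_, S))
  onset <- offset <- numeric(S)
  sx <- sy <- ex <- ey <- numeric(S)
  for (k in seq_len(S)) {
    i <- runs[[k]][1]:runs[[k]][2]
    onset[k] <- samples$t[i[1]]; offset[k] <- samples$t[i[length(i)]]
    sx[k] <- samples$x[i[1]]; sy[k] <- samples$y[i[1]]
    ex[k] <- samples$x[i[length(i)]]; ey[k] <- samples$y[i[length(i)]]
    stroke$duration_ms[k] <- offset[k] - onset[k]
    stroke$length[k] <- oracle_path_length(samples$x[i], samples$y[i])
    stroke$pressure[k] <- mean(samples$pressure[i])
    if (k > 1) {
      stroke$latency_ms[k] <- onset[k] - offset[k - 1]
      stroke$distance[k] <- sqrt((sx[k] - ex[k - 1])^2 + (sy[k] - ey[k - 1])^2)
    }
  }
  character <- if (S == 0) NULL else {
    ink <- samples$pressure > 0
    data.frame(latency_ms = onset[1] - audio_offset,
               duration_ms = offset[S] - onset[1],
               length = sum(stroke$length),
               pressure = mean(samples$pressure[ink]))
  }
  radical <- NULL
  if (!is.null(counts) && S == sum(counts)) {
    R <- length(counts)
    radical <- data.frame(latency_ms = rep(NA_real_, R),
                          duration_ms = rep(NA_real_, R),
                          length = rep(NA_real_, R),
                          pressure = rep(NA_real_, R),
                          distance = rep(NA_real_, R))
    hi <- cumsum(counts); lo <- hi - counts + 1L
    for (r in seq_len(R)) {
      ks <- lo[r]:hi[r]
      radical$duration_ms[r] <- offset[hi[r]] - onset[lo[r]]
      radical$length[r] <- sum(stroke$length[ks])
      npts <- 0; psum <- 0
      for (k in ks) {
        i <- runs[[k]][1]:runs[[k]][2]
        npts <- npts + length(i); psum <- psum + sum(samples$pressure[i])
      }
      radical$pressure[r] <- psum / npts
      if (r > 1) {
        radical$latency_ms[r] <- onset[lo[r]] - offset[hi[r - 1]]
        radical$distance[r] <- sqrt((sx[lo[r]] - ex[hi[r - 1]])^2 +
                                    (sy[lo[r]] - ey[hi[r - 1]])^2)
      }
    }
  }
  list(character = character, radical = radical, stroke = stroke,
       n_strokes = S)
}

# Benjamini-Hochberg step-up by direct search over the sorted p-values
oracle_bh_flags <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0L
  for (k in seq_len(m)) if (ps[k] <= k / m * q) kmax <- k
  flags <- rep(FALSE, m)
  if (kmax > 0L) flags[o[seq_len(kmax)]] <- TRUE
  flags
}

# a random pen-sample stream with integer timestamps and assorted edge
# shapes (leading/trailing ink, all-zero, isolated single-sample strokes)
random_stream <- function(n = NULL, trial_id = 1L) {
  if (is.null(n)) n <- sample(1:60, 1)
  p <- numeric(n)
  mode <- sample(1:4, 1)
  if (mode == 1) p <- sample(c(0, 0, 1, 5, 30000), n, replace = TRUE)
  if (mode == 2) p <- rep(0, n)                       # never touches down
  if (mode == 3) p <- sample(c(1, 9000), n, replace = TRUE)  # no hover at all
  if (mode == 4) {                                     # sparse blips
    p <- rep(0, n)
    p[sample(n, max(1, n %/% 8))] <- sample(1:100, max(1, n %/% 8), TRUE)
  }
  data.frame(trial_id = trial_id,
             t = cumsum(sample(1:12, n, replace = TRUE)),
             x = round(stats::rnorm(n, 0, 5), 3),
             y = round(stats::rnorm(n, 0, 5), 3),
             pressure = p)
}

# random composition of `total` into positive parts
random_counts <- function(total) {
  if (total == 1L) return(1L)
  r <- sample(seq_len(min(4L, total)), 1)
  if (r == 1L) return(total)
  cuts <- sort(sample(seq_len(total - 1L), r - 1L))
  as.integer(diff(c(0L, cuts, total)))
}
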