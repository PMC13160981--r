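# Vectorized pen-stream builder shared by simulate_trial() and
# simulate_dataset(). All trials are generated in bulk: stroke timing,
# polyline geometry, equal-arc-length resampling and hover interpolation are
# computed on concatenated per-stroke vectors, never per trial.

# cumulative sum restarting at each TRUE in `first` (internal)
group_cumsum <- function(x, first) {
  cs <- cumsum(x)
  base <- cs[which(first)] - x[which(first)]
  cs - rep(base, diff(c(which(first), length(x) + 1L)))
}

# Build every trial's pen-sample stream, times relative to each trial's
# audio offset at 0. `counts` is a list (per trial) of per-radical stroke
# counts; `latency` is the snapped character latency per trial; shifts are
# per-trial additive effects (ms) on radical gaps, stroke gaps and stroke
# durations; `circle` marks don't-know trials drawn as a single circle.
build_streams <- function(counts, latency, shift_rgap, shift_sgap,
                          shift_sdur, circle, config) {
  iv <- config$sampling_interval_ms
  n_trials <- length(counts)
  rad_pat <- counts
  rad_pat[!circle] <- lapply(counts[!circle],
                             function(cc) rep(seq_along(cc), cc))
  rad_pat[circle] <- list(1L)
  S <- lengths(rad_pat)
  total_S <- sum(S)
  st_trial <- rep(seq_len(n_trials), S)
  first_stroke <- c(TRUE, st_trial[-1] != st_trial[-total_S])
  rad <- unlist(rad_pat, use.names = FALSE)
  boundary <- c(FALSE, rad[-1] != rad[-total_S]) & !first_stroke

  # timing: snapped log-normal durations and gaps with per-item shifts
  durs <- snap(rlnorm_mean(total_S, config$stroke_dur_mean, config$dur_sdlog) +
                 shift_sdur[st_trial], iv)
  gap_mean <- ifelse(boundary, config$radical_gap_mean, config$stroke_gap_mean)
  gap_shift <- ifelse(boundary, shift_rgap[st_trial], shift_sgap[st_trial])
  gaps <- snap(rlnorm_mean(total_S, gap_mean, config$gap_sdlog) + gap_shift, iv)
  gaps[first_stroke] <- 0
  rel_end <- group_cumsum(durs + gaps, first_stroke)
  onset <- latency[st_trial] + rel_end - durs
  offset <- onset + durs
  n_s <- as.integer(round(durs / iv)) + 1L

  # geometry: per-stroke polylines (2-6 vertices; circles get 17), chained
  # by jump vectors whose length follows the stroke/radical distance model
  nv <- sample(2:6, total_S, replace = TRUE)
  nv[circle[st_trial]] <- 17L
  len <- pmax(0.5, stats::rnorm(total_S, config$stroke_len_mean,
                                config$stroke_len_sd))
  n_steps <- nv - 1L
  step_stroke <- rep(seq_len(total_S), n_steps)
  ang <- stats::runif(sum(n_steps), 0, 2 * pi)
  raw <- abs(stats::rnorm(sum(n_steps), 1, 0.4))
  sums <- rowsum(raw, step_stroke)[, 1]
  stepn <- raw / sums[step_stroke] * len[step_stroke]
  dx <- stepn * cos(ang)
  dy <- stepn * sin(ang)
  # circles: fixed increment pattern, radius 2
  if (any(circle)) {
    th <- seq(0, 2 * pi, length.out = 17)
    cpat_x <- diff(2 * cos(th)); cpat_y <- diff(2 * sin(th))
    cc <- circle[st_trial][step_stroke]
    dx[cc] <- rep(cpat_x, sum(circle))
    dy[cc] <- rep(cpat_y, sum(circle))
  }
  total_dx <- rowsum(dx, step_stroke)[, 1]
  total_dy <- rowsum(dy, step_stroke)[, 1]

  jump_d <- ifelse(boundary,
                   pmax(0.3, stats::rnorm(total_S, config$radical_dist_mean,
                                          config$radical_dist_sd)),
                   pmax(0.3, stats::rnorm(total_S, config$stroke_dist_mean,
                                          config$stroke_dist_sd)))
  jump_th <- stats::runif(total_S, 0, 2 * pi)
  jump_x <- jump_d * cos(jump_th); jump_y <- jump_d * sin(jump_th)
  jump_x[first_stroke] <- 0; jump_y[first_stroke] <- 0
  trial_origin_x <- stats::runif(n_trials, 2, 6)
  trial_origin_y <- stats::runif(n_trials, 2, 6)
  # start of stroke k = trial origin + sum over previous strokes of
  # (that stroke's net displacement + the jump into the next stroke)
  adv_x <- total_dx + c(jump_x[-1], 0)
  adv_y <- total_dy + c(jump_y[-1], 0)
  cum_x <- group_cumsum(adv_x, first_stroke)
  cum_y <- group_cumsum(adv_y, first_stroke)
  prev_adv_x <- c(0, cum_x[-total_S]); prev_adv_x[first_stroke] <- 0
  prev_adv_y <- c(0, cum_y[-total_S]); prev_adv_y[first_stroke] <- 0
  start_x <- trial_origin_x[st_trial] + prev_adv_x
  start_y <- trial_origin_y[st_trial] + prev_adv_y

  # vertex coordinates and within-stroke arc positions
  vx <- rep(start_x, nv); vy <- rep(start_y, nv)
  v_stroke <- rep(seq_len(total_S), nv)
  v_first <- c(TRUE, v_stroke[-1] != v_stroke[-length(v_stroke)])
  dxe <- numeric(length(vx)); dye <- numeric(length(vx))
  dxe[!v_first] <- dx; dye[!v_first] <- dy
  vx <- vx + group_cumsum(dxe, v_first)
  vy <- vy + group_cumsum(dye, v_first)
  seg <- sqrt(dxe^2 + dye^2)      # 0 at each stroke's first vertex
  arc <- group_cumsum(seg, v_first)
  arc_len <- arc[cumsum(nv)]      # total arc per stroke

  # equal-arc-length resampling on one global monotone axis
  pad_off <- cumsum(c(0, arc_len[-total_S] + 1))
  va <- arc + pad_off[v_stroke]
  samp_stroke <- rep(seq_len(total_S), n_s)
  j <- sequence(n_s)
  frac_arc <- (j - 1L) / pmax(rep(n_s, n_s) - 1L, 1L)
  pos <- frac_arc * arc_len[samp_stroke] + pad_off[samp_stroke]
  v_last <- cumsum(nv)
  v_first_idx <- v_last - nv + 1L
  idx <- findInterval(pos, va)
  idx <- pmin(pmax(idx, v_first_idx[samp_stroke]), v_last[samp_stroke] - 1L)
  den <- va[idx + 1L] - va[idx]
  w <- ifelse(den > 0, (pos - va[idx]) / den, 0)
  ink_x <- vx[idx] + w * (vx[idx + 1L] - vx[idx])
  ink_y <- vy[idx] + w * (vy[idx + 1L] - vy[idx])
  ink_t <- rep(onset, n_s) + (j - 1L) * iv
  ink_p <- pmax(1, stats::rnorm(length(ink_t), config$pressure_mean,
                                config$pressure_sd))

  # hover: 3 approach samples before each trial's first stroke, plus linear
  # pen-in-air interpolation inside each inter-stroke gap
  stroke_end_x <- vx[v_last]; stroke_end_y <- vy[v_last]
  gap_prev_end_x <- c(0, stroke_end_x[-total_S])
  gap_prev_end_y <- c(0, stroke_end_y[-total_S])
  m <- ifelse(first_stroke, 0L,
              pmax(0L, as.integer(round(gaps / iv)) - 1L))
  hov_stroke <- rep(seq_len(total_S), m)
  hj <- sequence(m)
  hfrac <- hj / (rep(m, m) + 1)
  hov_x <- gap_prev_end_x[hov_stroke] +
    hfrac * (start_x[hov_stroke] - gap_prev_end_x[hov_stroke])
  hov_y <- gap_prev_end_y[hov_stroke] +
    hfrac * (start_y[hov_stroke] - gap_prev_end_y[hov_stroke])
  prev_offset <- c(0, offset[-total_S])
  hov_t <- prev_offset[hov_stroke] + hj * iv

  fs_idx <- which(first_stroke)
  pre_t <- rep(onset[fs_idx], each = 3L) - rep(c(3, 2, 1) * iv, n_trials)
  pre_x <- rep(start_x[fs_idx], each = 3L)
  pre_y <- rep(start_y[fs_idx], each = 3L)

  t_all <- c(ink_t, hov_t, pre_t)
  trial_all <- c(st_trial[samp_stroke], st_trial[hov_stroke],
                 rep(seq_len(n_trials), each = 3L))
  o <- order(trial_all, t_all)
  samples <- data.frame(
    trial_id = trial_all[o],
    t = t_all[o],
    x = c(ink_x, hov_x, pre_x)[o],
    y = c(ink_y, hov_y, pre_y)[o],
    pressure = c(ink_p, rep(0, length(hov_t) + length(pre_t)))[o])

  list(samples = samples,
       strokes = data.frame(trial = st_trial, k = sequence(S), radical = rad,
                            onset = onset, offset = offset, duration = durs,
                            gap = ifelse(first_stroke, NA_real_, gaps)),
       last_ink_rel = offset[v_last_of_trial(st_trial, total_S)])
}

v_last_of_trial <- function(st_trial, total_S) {
  which(c(st_trial[-1] != st_trial[-total_S], TRUE))
}
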