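test_that("strokes are maximal pressure-positive runs", {
  s <- make_samples(c(0, 0, 3, 4, 0, 0, 5, 0))
  st <- detect_strokes(s)
  expect_equal(nrow(st), 2L)
  expect_equal(st$first_idx, c(3L, 7L))
  expect_equal(st$last_idx, c(4L, 7L))

  expect_equal(nrow(detect_strokes(make_samples(rep(0, 6)))), 0L)
  expect_equal(nrow(detect_strokes(make_samples(numeric(0)))), 0L)

  # no trailing hover: the stroke ends at the last sample
  st3 <- detect_strokes(make_samples(c(2, 2, 2)))
  expect_equal(nrow(st3), 1L)
  expect_equal(st3$last_idx, 3L)

  # minimum stroke size filters single-sample blips
  blip <- make_samples(c(0, 9, 0, 3, 3, 0))
  expect_equal(nrow(detect_strokes(blip)), 2L)
  expect_equal(detect_strokes(blip, min_stroke_samples = 2L)$first_idx, 4L)
})

test_that("path_length sums consecutive Euclidean distances", {
  expect_equal(path_length(c(0, 3), c(0, 4)), 5)
  expect_equal(path_length(c(0, 1, 1), c(0, 0, 1)), 2)
  expect_equal(path_length(0, 0), 0)
  expect_error(path_length(numeric(0), numeric(0)))
})

test_that("radical grouping follows the decomposition in writing order", {
  s <- make_samples(rep(c(1, 0), 13))  # 13 one-sample strokes
  st <- detect_strokes(s)
  expect_equal(nrow(st), 13L)
  rad <- group_radicals(st, c(5L, 8L))
  expect_equal(rad, rep(c(1L, 2L), c(5L, 8L)))
  expect_null(group_radicals(st[1:7, ], c(5L, 8L)))
  expect_equal(group_radicals(st[1:9, ], 9L), rep(1L, 9L))
})

test_that("segment_trial flags mismatches and missing decompositions", {
  s <- make_samples(c(0, 1, 0, 1, 0))
  expect_true("decomposition_mismatch" %in% segment_trial(s, c(5L, 8L))$flags)
  expect_true("missing_decomposition" %in% segment_trial(s)$flags)
  expect_true("no_ink" %in% segment_trial(make_samples(c(0, 0)), 1L)$flags)
})

test_that("character metrics follow the interval definitions", {
  # audio offset 1000, first touch 1500, last ink 3600
  s <- make_samples(c(0, 1, 1, 0, 1), t = c(1400, 1500, 2000, 2500, 3600),
                    x = c(0, 0, 3, 9, 9), y = c(0, 0, 4, 9, 9))
  tr <- segment_trial(s, c(1L, 1L))
  cm <- character_metrics(tr, audio_offset_ms = 1000)
  expect_equal(cm$latency_ms, 500)
  expect_equal(cm$duration_ms, 2100)
  # two strokes with lengths 5 and 0 sum to the character length
  expect_equal(cm$length, 5)
  expect_true(is.na(cm$distance))

  # uniform pressure: the character mean equals it exactly, hover excluded
  s2 <- make_samples(c(0, 12000, 12000, 0, 12000))
  cm2 <- character_metrics(segment_trial(s2), audio_offset_ms = 0)
  expect_equal(cm2$pressure, 12000)

  nink <- character_metrics(segment_trial(make_samples(c(0, 0))), 0)
  expect_true(is.na(nink$latency_ms))
  expect_match(nink$flags, "no_ink")
})

test_that("radical metrics are inter-unit intervals, undefined for radical 1", {
  # radical 1: strokes at t 1000-2000 ending at (0,0);
  # radical 2: one stroke starting t 2150 at (3,4)
  s <- make_samples(c(1, 1, 0, 1, 1),
                    t = c(1000, 2000, 2100, 2150, 2400),
                    x = c(0, 0, 2, 3, 3), y = c(5, 0, 0, 4, 4))
  tr <- segment_trial(s, c(1L, 1L))
  rm_ <- radical_metrics(tr)
  expect_equal(nrow(rm_), 2L)
  expect_true(is.na(rm_$latency_ms[1]) && is.na(rm_$distance[1]))
  expect_equal(rm_$latency_ms[2], 150)
  expect_equal(rm_$distance[2], 5)
  expect_equal(rm_$duration_ms, c(1000, 250))
  expect_equal(rm_$length, c(5, 0))

  # radical length is the sum of its member stroke lengths
  s2 <- make_samples(rep(c(1, 1, 0), 3),
                     x = c(0, 2, 0, 0, 3, 0, 0, 4, 0),
                     y = rep(0, 9))
  rm2 <- radical_metrics(segment_trial(s2, 3L))
  expect_equal(rm2$length, 2 + 3 + 4)
})

test_that("stroke metrics include gap, duration and jump distance", {
  s <- make_samples(c(1, 1, 0, 1, 1),
                    t = c(1500, 1600, 1650, 1700, 1850),
                    x = c(1, 1, 1, 0, 0), y = c(0, 0, 2, 0, 5))
  sm <- stroke_metrics(segment_trial(s))
  expect_equal(sm$latency_ms, c(NA, 100))
  expect_equal(sm$duration_ms, c(100, 150))
  # stroke 2 drawn (0,0)->(0,5): length 5; its start is 1 unit from the
  # previous stroke's end point (1,0)
  expect_equal(sm$length[2], 5)
  expect_equal(sm$distance[2], 1)
  # a stroke starting where the previous one ended has distance 0
  s0 <- make_samples(c(1, 0, 1), x = c(2, 9, 2), y = c(3, 9, 3))
  expect_equal(stroke_metrics(segment_trial(s0))$distance[2], 0)
})

test_that("segmentation matches the brute-force scan on random streams", {
  set.seed(61)
  for (i in 1:200) {
    s <- random_stream()
    runs <- oracle_stroke_runs(s$pressure)
    st <- detect_strokes(s)
    expect_equal(nrow(st), length(runs))
    if (length(runs)) {
      expect_equal(st$first_idx, vapply(runs, `[`, integer(1), 1))
      expect_equal(st$last_idx, vapply(runs, `[`, integer(1), 2))
    }
  }
})

test_that("metrics ignore prepended and appended hover samples", {
  set.seed(62)
  for (i in 1:25) {
    s <- random_stream(40)
    if (!any(s$pressure > 0)) next
    pre <- make_samples(rep(0, 3), t = s$t[1] - c(30, 20, 10),
                        x = stats::rnorm(3), y = stats::rnorm(3))
    post <- make_samples(rep(0, 2), t = s$t[40] + c(10, 20),
                         x = stats::rnorm(2), y = stats::rnorm(2))
    padded <- rbind(pre, s, post)
    a <- segment_trial(s); b <- segment_trial(padded)
    cols <- c("latency_ms", "duration_ms", "length", "pressure", "distance")
    expect_equal(stroke_metrics(b)[cols], stroke_metrics(a)[cols])
    expect_equal(character_metrics(b, 0)[cols], character_metrics(a, 0)[cols])
  }
})

test_that("the vectorized batch extraction equals the per-trial path", {
  sim <- small_sim()
  met <- extract_metrics(sim$samples, sim$events, sim$decomposition)
  set.seed(63)
  for (id in sample(sim$events$trial_id, 25)) {
    ev <- sim$events[sim$events$trial_id == id, ]
    counts <- sim$decomposition$radical_stroke_counts[[
      match(ev$target_char, sim$decomposition$character)]]
    tr <- segment_trial(sim$samples[sim$samples$trial_id == id, ], counts,
                        trial_id = id)
    sub <- met[met$trial_id == id, ]
    cols <- c("latency_ms", "duration_ms", "length", "pressure", "distance")
    expect_equal(sub[sub$level == "character", cols],
                 character_metrics(tr, ev$audio_offset_ms)[cols],
                 ignore_attr = TRUE)
    expect_equal(sub[sub$level == "stroke", cols], stroke_metrics(tr)[cols],
                 ignore_attr = TRUE)
    rm_ <- radical_metrics(tr)
    if (nrow(rm_))
      expect_equal(sub[sub$level == "radical", cols], rm_[cols],
                   ignore_attr = TRUE)
  }
})
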