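test_that("item aggregation averages within trial, then across participants", {
  ev <- make_events(trial_id = 1:2, participant_id = 1:2)
  rec <- rbind(
    data.frame(participant_id = 1L, item_number = 1L, target_char = "稻",
               trial_id = 1L, level = "radical", unit_index = 1:2,
               latency_ms = c(NA, 100), duration_ms = c(300, 500),
               length = 5, pressure = 100, distance = c(NA, 2), flags = ""),
    data.frame(participant_id = 1L, item_number = 1L, target_char = "稻",
               trial_id = 1L, level = "character", unit_index = 1L,
               latency_ms = 900, duration_ms = 800, length = 10,
               pressure = 100, distance = NA, flags = ""),
    data.frame(participant_id = 2L, item_number = 1L, target_char = "稻",
               trial_id = 2L, level = "character", unit_index = 1L,
               latency_ms = 1100, duration_ms = 1000, length = 12,
               pressure = 100, distance = NA, flags = ""),
    data.frame(participant_id = 2L, item_number = 1L, target_char = "稻",
               trial_id = 2L, level = "radical", unit_index = 1:2,
               latency_ms = c(NA, 200), duration_ms = c(400, 600),
               length = 5, pressure = 100, distance = c(NA, 4), flags = ""))
  items <- aggregate_items(rec, ev)
  expect_equal(items$character_latency, 1000)      # mean of 900, 1100
  expect_equal(items$radical_latency, 150)         # trial means 100 and 200
  expect_equal(items$radical_duration, mean(c(400, 500)))
  expect_equal(items$radical_distance, 3)
  expect_equal(items$n_trials, 2L)
})

test_that("aggregation is invariant to participant relabeling", {
  sim <- small_sim()
  met <- extract_metrics(sim$samples, sim$events, sim$decomposition)
  a <- aggregate_items(met, sim$events)
  ev2 <- sim$events
  perm <- sample(unique(ev2$participant_id))
  ev2$participant_id <- perm[match(ev2$participant_id,
                                   unique(ev2$participant_id))]
  met2 <- met
  met2$participant_id <- perm[match(met2$participant_id,
                                    unique(sim$events$participant_id))]
  b <- aggregate_items(met2, ev2)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("spearman_brown is the closed-form step-up and is monotone", {
  expect_equal(spearman_brown(0.9), 2 * 0.9 / 1.9)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  r <- seq(-0.95, 1, by = 0.05)
  expect_equal(spearman_brown(r), 2 * r / (1 + r))
  expect_true(all(diff(spearman_brown(r)) > 0))
  expect_error(spearman_brown(-1))
})

test_that("split-half reliability is 1 for duplicated halves, ~0 for noise", {
  # participants 1/2 are exact copies of 3/4: every split pairs identical
  # item vectors
  items <- sprintf("it%03d", 1:50)
  vals <- stats::rnorm(50)
  tt <- data.frame(participant_id = rep(1:4, each = 50),
                   target_char = rep(items, 4), y = rep(vals, 4))
  res <- split_half_reliability(tt, "y", seed = 1)
  expect_equal(res$r_half, 1)
  expect_equal(res$r_corrected, 1)

  # pure noise, many items: corrected r near 0
  set.seed(99)
  tt2 <- data.frame(participant_id = rep(1:10, each = 1200),
                    target_char = rep(sprintf("c%04d", 1:1200), 10),
                    y = stats::rnorm(12000))
  res2 <- split_half_reliability(tt2, "y", seed = 5)
  expect_lt(abs(res2$r_corrected), 0.1)
})

test_that("split-half handles odd participant counts and fixed seeds", {
  tt <- data.frame(participant_id = rep(1:5, each = 30),
                   target_char = rep(sprintf("c%02d", 1:30), 5),
                   y = stats::rnorm(150))
  a <- split_half_reliability(tt, "y", seed = 7)
  b <- split_half_reliability(tt, "y", seed = 7)
  expect_false(is.null(a$dropped_participant))
  expect_equal(a$r_corrected, b$r_corrected)
})

test_that("ICC(A,1) is 1 for perfect agreement and ~0 for noise", {
  m <- matrix(rep(stats::rnorm(60), 3), ncol = 3)
  expect_equal(icc_agreement(m)$icc, 1)
  set.seed(17)
  noise <- matrix(stats::runif(1500), ncol = 3)
  res <- icc_agreement(noise)
  expect_lt(abs(res$icc), 0.1)
  expect_lt(res$ci[1], res$icc)
  expect_gt(res$ci[2], res$icc)
  expect_error(icc_agreement(matrix(1, 10, 3)), "constant")
})

test_that("correlation matrix mixes Pearson and phi with stars", {
  # binary pair from a 2x2 table with counts (10,0;0,10): phi = 1
  b1 <- rep(c(-0.5, 0.5), each = 10)
  ct <- correlation_matrix(data.frame(a = b1, b = b1))
  expect_equal(ct$r["a", "b"], 1)
  expect_equal(ct$r["a", "a"], 1)
  # balanced 2x2 (25,25;25,25): phi = 0
  b2 <- data.frame(a = rep(c(-0.5, 0.5), each = 50),
                   b = rep(c(-0.5, 0.5, -0.5, 0.5), each = 25))
  expect_equal(correlation_matrix(b2)$r["a", "b"], 0)
  # phi equals Pearson equals cor() on the sum-coded columns
  set.seed(3)
  x <- sample(c(-0.5, 0.5), 80, TRUE); y <- sample(c(-0.5, 0.5), 80, TRUE)
  expect_equal(correlation_matrix(data.frame(x, y))$r["x", "y"], cor(x, y))
  # stars match cor.test
  set.seed(4)
  u <- stats::rnorm(100); v <- u + stats::rnorm(100, 0, 0.5)
  ctt <- correlation_matrix(data.frame(u, v))
  expect_equal(ctt$p["u", "v"], stats::cor.test(u, v)$p.value)
  expect_equal(ctt$stars["u", "v"], "***")
  # zero variance is reported, not an error
  zv <- correlation_matrix(data.frame(k = rep(1, 10), u = stats::rnorm(10)))
  expect_equal(zv$zero_variance, "k")
})

test_that("VIF screening matches the closed form and car::vif", {
  set.seed(21)
  # predictors orthogonal to each other and to the intercept: all VIFs 1
  X <- as.data.frame(qr.Q(qr(cbind(1, matrix(stats::rnorm(400), 100, 4))))[, -1])
  names(X) <- c("a", "b", "c", "d")
  res <- vif_screen(X)
  expect_equal(unname(res$vif), rep(1, 4), tolerance = 1e-8)
  expect_equal(sort(res$retained), c("a", "b", "c", "d"))

  # two predictors with correlation r: VIF = 1/(1-r^2); r = 0.9 exceeds 5
  n <- 5000
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  r <- 0.9
  x2 <- r * z1 + sqrt(1 - r^2) * z2
  # construct exact sample correlation via residual orthogonalization
  e <- stats::residuals(stats::lm(x2 ~ z1))
  x2 <- r * scale(z1)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  X2 <- data.frame(p = scale(z1)[, 1], q = x2)
  v <- vif_screen(X2, threshold = 5)
  expect_equal(max(v$steps[[1]]), 1 / (1 - r^2), tolerance = 1e-6)
  expect_length(v$dropped, 1)

  # exact duplicate: infinite VIF, dropped with a warning
  X3 <- data.frame(a = z1, b = z1, c = stats::rnorm(n))
  expect_warning(v3 <- vif_screen(X3), "collinear")
  expect_equal(v3$dropped, "a")  # alphabetical tie-break

  # cross-check initial VIFs against car::vif on a random design
  skip_if_not_installed("car")
  set.seed(22)
  D <- as.data.frame(matrix(stats::rnorm(600), 100, 6))
  D$V1 <- D$V2 * 0.8 + D$V1 * 0.3
  y <- stats::rnorm(100)
  fit <- stats::lm(y ~ ., data = D)
  expect_equal(vif_screen(D, threshold = Inf)$vif, car::vif(fit),
               tolerance = 1e-10)
})

test_that("VIF screening is order-independent for orthogonal predictors", {
  set.seed(23)
  X <- as.data.frame(qr.Q(qr(cbind(1, matrix(stats::rnorm(300), 100, 3))))[, -1])
  names(X) <- c("a", "b", "c")
  expect_equal(sort(vif_screen(X)$retained),
               sort(vif_screen(X[c(3, 1, 2)])$retained))
})

test_that("FDR flags sit between Bonferroni and unadjusted thresholds", {
  expect_equal(as.logical(fdr_adjust(c(0.001, 0.02, 0.04))),
               oracle_bh_flags(c(0.001, 0.02, 0.04)))
  expect_equal(as.logical(fdr_adjust(c(0.9, 0.95))), c(FALSE, FALSE))
  expect_true(fdr_adjust(0.01)[1])
  expect_false(fdr_adjust(0.07)[1])
  set.seed(31)
  for (i in 1:50) {
    p <- stats::runif(sample(1:20, 1))^sample(1:3, 1)
    flags <- as.logical(fdr_adjust(p))
    expect_equal(flags, oracle_bh_flags(p))
    bonf <- p <= 0.05 / length(p)
    expect_true(all(flags[bonf]))          # superset of Bonferroni
    expect_true(all(p[flags] <= 0.05))     # subset of raw p < q
  }
})
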