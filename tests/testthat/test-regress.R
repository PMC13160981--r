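# item/norm pair with a designed outcome, built directly (no pipeline)
make_item_norms <- function(n = 200, seed = 123) {
  set.seed(seed)
  cfg <- sim_config(n_items = n, seed = seed)
  stim <- simulate_norms(cfg)
  items <- data.frame(target_char = stim$norms$character,
                      stringsAsFactors = FALSE)
  list(items = items, norms = stim$norms, z = stim$z)
}

test_that("zero-noise outcomes recover their generating coefficients", {
  d <- make_item_norms()
  d$items$character_latency <- 2 * d$z[, "frequency"]
  # zero residual noise: lm warns about a perfect fit, which is the point
  fit <- suppressWarnings(
    fit_item_regression(d$items, d$norms, "character_latency"))
  co <- coef(fit)
  expect_equal(unname(co["frequency"]), 2, tolerance = 1e-8)
  others <- setdiff(lexical_predictors(), "frequency")
  expect_lt(max(abs(co[others])), 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # only frequency is flagged
  sig <- fit$coefficients$sig[fit$coefficients$term %in% lexical_predictors()]
  expect_equal(sum(sig), 1L)
})

test_that("an outcome identical to a covariate gives R^2 = 1", {
  d <- make_item_norms(n = 150, seed = 4)
  d$items$stroke_distance <- stats::rnorm(150)
  d$items$stroke_latency <- 3 + 5 * d$items$stroke_distance
  fit <- suppressWarnings(
    fit_item_regression(d$items, d$norms, "stroke_latency"))
  expect_equal(fit$covariates, "stroke_distance")  # footnote covariate
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("FDR family covers exactly the 14 lexical terms", {
  d <- make_item_norms(n = 180, seed = 9)
  d$items$character_duration <- stats::rnorm(180)
  d$items$character_length <- stats::rnorm(180)
  d$items$stroke_distance <- stats::rnorm(180)
  d$items$stroke_latency <- stats::rnorm(180)
  fit <- fit_item_regression(d$items, d$norms, "character_duration")
  co <- fit$coefficients
  expect_setequal(co$term[!is.na(co$p_fdr)], lexical_predictors())
  expect_true(all(c("(Intercept)", "character_length", "stroke_distance",
                    "stroke_latency") %in% co$term))
  # the BH flags over the family match the oracle
  fam <- co$term %in% lexical_predictors()
  expect_equal(co$sig[fam], oracle_bh_flags(co$p[fam]))
})

test_that("regressions refuse underdetermined designs", {
  d <- make_item_norms(n = 200, seed = 5)
  d$items$character_latency <- stats::rnorm(200)
  expect_error(fit_item_regression(d$items[1:10, ], d$norms,
                                   "character_latency"), "too few")
})

test_that("a pure additive level shift loads only on the Level term", {
  d <- make_item_norms(n = 160, seed = 31)
  base <- 100 + 3 * d$z[, "frequency"]
  d$items$character_latency <- base + 250   # shift of +250 at the character level
  d$items$radical_latency <- base - 250
  fit <- suppressWarnings(
    fit_level_contrast(d$items, d$norms, "latency",
                       c("character", "radical")))
  co <- coef(fit)
  expect_equal(unname(co["Level"]), 500, tolerance = 1e-8)
  ints <- grep("^Level:", names(co), value = TRUE)
  expect_lt(max(abs(co[ints])), 1e-6)
  # z-scoring happens on the stacked sample, so the slope is recovered up to
  # the (2n vs n)-sample SD ratio, a ~0.2% rescaling
  expect_equal(unname(co["frequency"]), 3, tolerance = 0.01)
})

test_that("identical outcomes at both levels zero the Level term", {
  d <- make_item_norms(n = 140, seed = 32)
  y <- stats::rnorm(140)
  d$items$character_latency <- y
  d$items$stroke_latency <- y
  fit <- fit_level_contrast(d$items, d$norms, "latency",
                            c("character", "stroke"))
  expect_equal(unname(coef(fit)["Level"]), 0, tolerance = 1e-10)
})

test_that("cascaded attenuation is recovered as a Level x predictor effect", {
  # effect b at the higher level, b/2 at the lower level: the interaction
  # coefficient should recover b - b/2 = b/2
  b <- 40
  reps <- 40
  est <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    d <- make_item_norms(n = 150, seed = 1000 + i)
    noise <- function() stats::rnorm(150, 0, 10)
    d$items$character_latency <- 500 + b * d$z[, "frequency"] + noise()
    d$items$radical_latency <- 150 + b / 2 * d$z[, "frequency"] + noise()
    fit <- fit_level_contrast(d$items, d$norms, "latency",
                              c("character", "radical"))
    est[i, ] <- coef(fit)[c("frequency", "Level:frequency")]
  }
  mc_se <- apply(est, 2, stats::sd) / sqrt(reps)
  # main effect ~ the cross-level mean 0.75 b; interaction ~ b/2
  expect_lt(abs(mean(est[, 1]) - 0.75 * b), 2 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - b / 2), 2 * mc_se[2])
  expect_gt(mean(est[, 2]), 0)
})

test_that("duration contrasts include Length and Level:Length", {
  d <- make_item_norms(n = 150, seed = 33)
  d$items$character_duration <- stats::rnorm(150, 2200, 100)
  d$items$radical_duration <- stats::rnorm(150, 700, 50)
  d$items$character_length <- stats::rnorm(150, 40, 5)
  d$items$radical_length <- stats::rnorm(150, 15, 3)
  fit <- fit_level_contrast(d$items, d$norms, "duration",
                            c("character", "radical"))
  expect_true(all(c("Length", "Level:Length") %in% fit$coefficients$term))
  # Length and Level:Length are covariates, outside the FDR family
  expect_true(all(is.na(
    fit$coefficients$p_fdr[fit$coefficients$term %in%
                             c("Length", "Level:Length")])))
})

test_that("items missing one level are dropped with a message", {
  d <- make_item_norms(n = 120, seed = 34)
  d$items$character_latency <- stats::rnorm(120)
  d$items$radical_latency <- stats::rnorm(120)
  d$items$radical_latency[1:5] <- NA
  expect_message(
    fit <- fit_level_contrast(d$items, d$norms, "latency",
                              c("character", "radical")),
    "5 item")
  expect_equal(fit$n, 115)
})
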