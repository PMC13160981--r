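#' Default covariates per outcome
#'
#' The execution-side outcomes are adjusted for mechanical determinants of
#' writing time before interpreting lexical effects: character duration for
#' character length, stroke distance and stroke latency; radical latency for
#' radical distance; radical duration for radical length and stroke latency;
#' stroke latency for stroke distance; stroke duration for stroke length and
#' stroke distance. Amnesia rate and character latency take none.
#'
#' @param outcome Item-summary column name.
#' @return Character vector of covariate column names (possibly empty).
#' @export
default_covariates <- function(outcome) {
  switch(outcome,
    character_duration = c("character_length", "stroke_distance",
                           "stroke_latency"),
    radical_latency = "radical_distance",
    radical_duration = c("radical_length", "stroke_latency"),
    stroke_latency = "stroke_distance",
    stroke_duration = c("stroke_length", "stroke_distance"),
    character())
}

# z-transform columns using the analysis sample's mean/SD (internal)
z_cols <- function(df, cols) {
  for (col in cols) df[[col]] <- as.numeric(scale(df[[col]]))
  df
}

#' Item-level multiple regression with FDR-corrected lexical effects
#'
#' Ordinary least squares of an item-level outcome on the 14 lexical
#' predictors (all z-transformed on the analysis sample) plus any covariates.
#' Benjamini-Hochberg correction at `q` is applied over the family of the 14
#' lexical predictor terms of this model; the intercept and covariates are
#' exempt (their raw p-values are reported).
#'
#' @param items Item summary from [aggregate_items()].
#' @param norms Lexical norms table (one row per character).
#' @param outcome Outcome column in `items` (e.g. `"character_latency"`,
#'   `"amnesia_rate"`).
#' @param covariates Covariate columns in `items`;
#'   `default_covariates(outcome)` by default. Covariates are z-transformed
#'   like the predictors.
#' @param q FDR level (default .05).
#' @return Object of class `item_regression`: `coefficients` (data frame
#'   with `term`, `beta`, `t`, `p`, `p_fdr`, `sig`), `r_squared`, `outcome`,
#'   `covariates`, `n`, and the underlying `lm` fit.
#' @export
fit_item_regression <- function(items, norms, outcome,
                                covariates = default_covariates(outcome),
                                q = 0.05) {
  preds <- lexical_predictors()
  d <- merge(items[c("target_char", outcome, covariates)], norms,
             by.x = "target_char", by.y = "character")
  d <- d[stats::complete.cases(d[c(outcome, covariates, preds)]), , drop = FALSE]
  terms <- c(preds, covariates)
  if (nrow(d) <= length(terms) + 1L)
    stop("too few complete items (", nrow(d), ") for ", length(terms), " terms")
  d <- z_cols(d, terms)
  fml <- stats::reformulate(terms, response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), beta = sm[, 1], t = sm[, 3],
                   p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  fam <- co$term %in% preds
  flags <- fdr_adjust(co$p[fam], q)
  co$p_fdr <- NA_real_
  co$p_fdr[fam] <- attr(flags, "p_adjusted")
  co$sig <- co$p < q
  co$sig[fam] <- as.logical(flags)
  structure(list(coefficients = co, r_squared = summary(fit)$r.squared,
                 outcome = outcome, covariates = covariates, n = nrow(d),
                 q = q, fit = fit),
            class = "item_regression")
}

#' @export
print.item_regression <- function(x, digits = 3, ...) {
  cat("Item-level regression of", x$outcome,
      sprintf("(N = %d items, R^2 = %.3f)\n", x$n, x$r_squared))
  if (length(x$covariates))
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  co <- x$coefficients
  co$beta <- signif(co$beta, digits); co$t <- round(co$t, 2)
  co$p <- format.pval(co$p, digits = 2, eps = 1e-3)
  co$sig <- ifelse(co$sig, "*", "")
  print(co, row.names = FALSE)
  cat("* significant after Benjamini-Hochberg FDR at q =", x$q,
      "(lexical terms; raw p for intercept/covariates)\n")
  invisible(x)
}

#' @export
coef.item_regression <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' Cross-level contrast regression (Level x predictor interactions)
#'
#' Stacks the item-level outcome at two orthographic levels (one row per
#' item per level), codes Level as -0.5 (lower unit) / +0.5 (higher unit),
#' and fits OLS with the 14 lexical main effects, the Level main effect, and
#' all Level x predictor interactions. With `Level` coded this way its
#' coefficient equals the between-level difference and an interaction
#' coefficient is the between-level difference in that predictor's effect --
#' the quantity of interest under the cascaded-attenuation hypothesis.
#' Duration contrasts additionally adjust for the level-specific trace
#' length (`Length` and `Level:Length`). FDR correction is applied over the
#' family of the 14 main-effect terms plus their 14 interactions.
#'
#' @param items Item summary from [aggregate_items()].
#' @param norms Lexical norms table.
#' @param measure `"latency"` or `"duration"`.
#' @param levels Character vector of two unit levels, higher first (e.g.
#'   `c("character", "radical")`).
#' @param q FDR level.
#' @return Object of class `level_contrast` (same fields as
#'   [fit_item_regression()] plus `levels` and `measure`).
#' @export
fit_level_contrast <- function(items, norms, measure = c("latency", "duration"),
                               levels = c("character", "radical"), q = 0.05) {
  measure <- match.arg(measure)
  stopifnot(length(levels) == 2)
  preds <- lexical_predictors()
  cols <- paste0(levels, "_", measure)
  miss <- setdiff(cols, names(items))
  if (length(miss)) stop("items lacks column(s): ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(items[cols])
  if (any(!keep))
    message(sum(!keep), " item(s) missing one level dropped from the ",
            paste(levels, collapse = " vs "), " contrast")
  it <- items[keep, , drop = FALSE]
  long <- data.frame(
    target_char = rep(it$target_char, 2L),
    outcome = c(it[[cols[1]]], it[[cols[2]]]),
    Level = rep(c(0.5, -0.5), each = nrow(it)),
    stringsAsFactors = FALSE)
  if (measure == "duration") {
    lcols <- paste0(levels, "_length")
    long$Length <- c(it[[lcols[1]]], it[[lcols[2]]])
  }
  d <- merge(long, norms, by.x = "target_char", by.y = "character")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d <- z_cols(d, c(preds, if (measure == "duration") "Length"))
  rhs <- paste0("Level * (", paste(preds, collapse = " + "), ")")
  if (measure == "duration") rhs <- paste(rhs, "+ Length + Level:Length")
  fit <- stats::lm(stats::as.formula(paste("outcome ~", rhs)), data = d)
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), beta = sm[, 1], t = sm[, 3],
                   p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  fam <- co$term %in% c(preds, paste0("Level:", preds))
  flags <- fdr_adjust(co$p[fam], q)
  co$p_fdr <- NA_real_
  co$p_fdr[fam] <- attr(flags, "p_adjusted")
  co$sig <- co$p < q
  co$sig[fam] <- as.logical(flags)
  structure(list(coefficients = co, r_squared = summary(fit)$r.squared,
                 measure = measure, levels = levels, n = nrow(it), q = q,
                 fit = fit),
            class = "level_contrast")
}

#' @export
print.level_contrast <- function(x, digits = 3, ...) {
  cat(sprintf("Level contrast (%s vs. %s) on writing %s: N = %d items, R^2 = %.3f\n",
              x$levels[1], x$levels[2], x$measure, x$n, x$r_squared))
  co <- x$coefficients
  co$beta <- signif(co$beta, digits); co$t <- round(co$t, 2)
  co$p <- format.pval(co$p, digits = 2, eps = 1e-3)
  co$sig <- ifelse(co$sig, "*", "")
  print(co, row.names = FALSE)
  invisible(x)
}

#' @export
coef.level_contrast <- coef.item_regression
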