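# Respiration arithmetic, response ratios, DOM-content PC1 and the
# regression / ANOVA layer linking photochemical change to biodegradation.

#' Blank-corrected microbial CO2 production
#'
#' Production over an incubation interval is the rise in cumulative headspace
#' CO2 from day 0 (the background DIC measurement) to the given day, minus
#' the same rise in the sterile blank. Negative results are retained (they
#' reflect measurement noise around zero) and flagged via the `"negative"`
#' attribute. Without a blank the uncorrected value is returned with a
#' warning.
#'
#' @param record One-row slice of a [sample_table()] (or a list with
#'   `co2_d0` and `co2_d7`/`co2_d28`).
#' @param blank Matching blank record, or `NULL`.
#' @param day Incubation day, 7 or 28.
#' @return CO2 production in umol.
#' @export
co2_production <- function(record, blank = NULL, day = 28) {
  stopifnot(day %in% c(7, 28))
  col <- paste0("co2_d", day)
  v <- record[[col]]; v0 <- record[["co2_d0"]]
  if (is.null(v) || is.na(v) || is.null(v0) || is.na(v0))
    stop(sprintf("day %d and day 0 CO2 measurements are both required", day))
  prod <- v - v0
  if (is.null(blank)) {
    warning("no blank record supplied; returning uncorrected production")
  } else {
    b <- blank[[col]]; b0 <- blank[["co2_d0"]]
    if (is.null(b) || is.na(b) || is.null(b0) || is.na(b0))
      stop(sprintf("blank is missing a day %d or day 0 measurement", day))
    prod <- prod - (b - b0)
  }
  prod <- unname(prod)
  if (prod < 0) attr(prod, "negative") <- TRUE
  prod
}

#' Log response ratio
#'
#' RR = ln(treatment mean / control mean), the standard effect measure for
#' the sunlight treatment; 0 means no effect, positive values mean sunlight
#' enhanced the response.
#'
#' @param treatment_mean,control_mean Positive means (vectorised).
#' @param log Compute the log ratio (default) or the plain ratio.
#' @return Numeric response ratio; `NA` with a warning when either mean is
#'   non-positive.
#' @export
response_ratio <- function(treatment_mean, control_mean, log = TRUE) {
  bad <- !is.finite(treatment_mean) | !is.finite(control_mean) |
    treatment_mean <= 0 | control_mean <= 0
  if (any(bad))
    warning("non-positive mean(s); response ratio undefined there")
  r <- ifelse(bad, NA_real_, treatment_mean / control_mean)
  if (log) log(r) else r
}

#' DOM-content score: PC1 of standardized DOC and DON
#'
#' Both variables are z-scored, the 2x2 correlation matrix is
#' eigen-decomposed and the first-component scores are returned, oriented so
#' the DOC loading is positive. For two variables the variance explained has
#' the closed form (1 + |r|) / 2.
#'
#' @param doc_values,don_values Per-lake DOC and DON concentrations (same
#'   length, >= 3, each with nonzero variance).
#' @return A list with `scores` (PC1 score per lake, variance =
#'   eigenvalue), `loadings`, `var_explained` and `r` (the DOC-DON Pearson
#'   correlation).
#' @export
dom_pc1 <- function(doc_values, don_values) {
  stopifnot(length(doc_values) == length(don_values),
            length(doc_values) >= 3)
  if (stats::sd(doc_values) == 0 || stats::sd(don_values) == 0)
    stop("DOC and DON must both have nonzero variance")
  z <- cbind(doc = as.vector(scale(doc_values)),
             don = as.vector(scale(don_values)))
  ev <- eigen(stats::cor(z), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  if (v1[1] < 0) v1 <- -v1
  list(scores = as.vector(z %*% v1),
       loadings = stats::setNames(v1, c("doc", "don")),
       var_explained = ev$values[1] / sum(ev$values),
       r = stats::cor(z[, 1], z[, 2]))
}

#' Standardized regression coefficient
#'
#' OLS of z(y) on z(x); the slope equals the Pearson correlation, with the
#' usual two-sided t test on n - 2 degrees of freedom and R^2 = r^2.
#'
#' @param x,y Numeric vectors (n >= 3, finite, nonzero variance).
#' @return A list: `coef`, `p_value`, `r2`, `n`.
#' @export
standardized_coef <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 complete observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("x and y must both have nonzero variance")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(coef = r, p_value = p, r2 = r^2, n = n)
}

#' Factorial ANOVA with type-II sums of squares
#'
#' Fits a fully crossed linear model of `response` on the requested factors
#' and returns the type-II ANOVA table (equal to type I/III on a balanced
#' design). Interaction terms keep their `A:B` names so the
#' sunlight-by-temperature and sunlight-by-lake terms can be read off
#' directly. A response with zero variance yields `NA` F and p values with a
#' `degenerate` flag rather than an error.
#'
#' @param table Long-format data frame with a numeric `response` column and
#'   one column per factor.
#' @param factors Character vector naming >= 2-level factor columns, e.g.
#'   `c("treatment", "temperature", "lake")`.
#' @return Data frame: `term`, `sumsq`, `df`, `statistic`, `p_value`, plus a
#'   `degenerate` attribute.
#' @export
factorial_anova <- function(table,
                            factors = c("treatment", "temperature", "lake")) {
  stopifnot(is.data.frame(table), "response" %in% names(table),
            all(factors %in% names(table)))
  for (f in factors) {
    table[[f]] <- factor(table[[f]])
    if (nlevels(table[[f]]) < 2)
      stop(sprintf("factor '%s' has fewer than 2 levels", f))
  }
  degenerate <- stats::sd(table$response) == 0
  fml <- stats::as.formula(paste("response ~", paste(factors, collapse = "*")))
  fit <- stats::lm(fml, data = table)
  a <- if (degenerate) {
    suppressWarnings(try(car::Anova(fit, type = 2), silent = TRUE))
  } else {
    car::Anova(fit, type = 2)
  }
  if (inherits(a, "try-error")) {
    terms <- attr(stats::terms(fit), "term.labels")
    out <- data.frame(term = terms, sumsq = 0, df = NA_integer_,
                      statistic = NA_real_, p_value = NA_real_)
  } else {
    a <- as.data.frame(a)
    keep <- rownames(a) != "Residuals"
    out <- data.frame(term = rownames(a)[keep],
                      sumsq = a[keep, "Sum Sq"],
                      df = a[keep, "Df"],
                      statistic = a[keep, "F value"],
                      p_value = a[keep, "Pr(>F)"])
    if (degenerate) out$statistic <- out$p_value <- NA_real_
  }
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-values for small samples (combined n <= 20, no ties), normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return A list: `statistic` (rank-sum W), `p_value`.
#' @export
group_rank_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  exact <- (length(a) + length(b)) <= 20 &&
    !anyDuplicated(c(a, b))
  w <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact))
  list(statistic = unname(w$statistic), p_value = w$p.value)
}
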