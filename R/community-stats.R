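# Community-level trait statistics: sorting-temperature regression
# comparison, trait PCA, power-law scaling, rank-sum phylum contrasts.

#' Compare quadratic against straight-line regression
#'
#' Fits `y ~ x` and `y ~ x + x^2` by ordinary least squares and tests
#' whether the quadratic term improves the fit with the nested F-test
#' `F = (RSS1 - RSS2) / (RSS2 / (n - 3))` on (1, n - 3) degrees of
#' freedom.  Used to ask whether thermal optima deviate from a straight
#' line across sorting temperatures (curvature = cold-end mismatch).
#'
#' @param x predictor (e.g. sorting temperature, degC).
#' @param y response (e.g. thermal optimum, degC).
#' @return an object of class `"model_comparison"`: list with
#'   `rss_linear`, `rss_quadratic`, `f_statistic`, `df = c(1, n - 3)`,
#'   `p_value`, `coef_linear`, `coef_quadratic`, `r_squared_linear`,
#'   `r_squared_quadratic`, `n`, and the two `lm` fits.
#' @export
quadratic_vs_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("at least 4 complete observations are required")
  if (length(unique(x)) < 3)
    stop("x must take at least 3 distinct values for a quadratic fit")
  m1 <- stats::lm(y ~ x)
  m2 <- stats::lm(y ~ x + I(x^2))
  rss1 <- sum(stats::residuals(m1)^2)
  rss2 <- sum(stats::residuals(m2)^2)
  f <- (rss1 - rss2) / (rss2 / (n - 3))
  p <- stats::pf(f, 1, n - 3, lower.tail = FALSE)
  structure(list(
    rss_linear = rss1, rss_quadratic = rss2,
    f_statistic = f, df = c(1, n - 3), p_value = p,
    coef_linear = stats::coef(m1), coef_quadratic = stats::coef(m2),
    r_squared_linear = summary(m1)$r.squared,
    r_squared_quadratic = summary(m2)$r.squared,
    n = n, fit_linear = m1, fit_quadratic = m2
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Quadratic vs straight-line regression (nested F-test)\n")
  cat(sprintf("  n = %d; RSS linear = %.4g, RSS quadratic = %.4g\n",
              x$n, x$rss_linear, x$rss_quadratic))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat(sprintf("  R^2: linear %.3f, quadratic %.3f\n",
              x$r_squared_linear, x$r_squared_quadratic))
  invisible(x)
}

#' Principal components analysis of life-history traits
#'
#' PCA of the selected trait columns after standardization to mean 0
#' and SD 1, via [stats::prcomp].  Eigenvector signs are arbitrary; for
#' determinism each component is flipped so its largest-magnitude
#' loading is positive.
#'
#' @param table data.frame of traits, one row per isolate.
#' @param variables character vector of >= 2 column names to include.
#' @param row_filter optional logical vector selecting rows (e.g. to
#'   restrict to particular phyla).
#' @return an object of class `"trait_pca"`: list with `loadings`
#'   (variables x components), `explained_variance_fraction`, `scores`
#'   (isolates x components), `center`, `scale`, `n`.
#' @export
pca_traits <- function(table,
                       variables = c("topt", "niche_width", "mu_max",
                                     "r_max", "log_atp",
                                     "carrying_capacity"),
                       row_filter = NULL) {
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols))
    stop("missing trait column(s): ", paste(missing_cols, collapse = ", "))
  if (length(variables) < 2) stop("at least 2 variables are required")
  if (!is.null(row_filter)) table <- table[row_filter, , drop = FALSE]
  m <- as.matrix(table[, variables])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("at least 3 complete rows are required")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  # deterministic sign: largest |loading| per component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  structure(list(
    loadings = pc$rotation,
    explained_variance_fraction = ev / sum(ev),
    scores = pc$x,
    center = pc$center, scale = pc$scale,
    n = nrow(m)
  ), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, digits = 3, ...) {
  cat(sprintf("Trait PCA (%d isolates, %d variables)\n",
              x$n, nrow(x$loadings)))
  frac <- x$explained_variance_fraction
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(frac), 100 * frac),
            collapse = ", "), "\n")
  cat(sprintf("  first two components: %.1f%% cumulative\n",
              100 * sum(frac[1:min(2, length(frac))])))
  print(round(x$loadings, digits))
  invisible(x)
}

#' Power-law (log-log) scaling fit
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`; the slope is the
#' scaling exponent.  Used for the ATP-respiration scaling relationship
#' (exponent 1 = linear scaling, < 1 = sublinear).
#'
#' @param x positive predictor values (e.g. respiration rates).
#' @param y positive response values (e.g. ATP content).
#' @return an object of class `"powerlaw_fit"`: list with `exponent`,
#'   `exponent_se`, `intercept` (log10 scale), `r_squared`, `p_value`,
#'   `n`, and the underlying `lm` fit.
#' @export
powerlaw_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad))
    stop("non-positive or non-finite values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (length(x) < 3) stop("at least 3 observations are required")
  fit <- stats::lm(log10(y) ~ log10(x))
  sm <- summary(fit)
  structure(list(
    exponent = unname(stats::coef(fit)[2]),
    exponent_se = unname(sm$coefficients[2, 2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    n = length(x), fit = fit
  ), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: exponent = %.2f +/- %.2f (R^2 = %.2f, n = %d, p = %.3g)\n",
    x$exponent, x$exponent_se, x$r_squared, x$n, x$p_value))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Wrapper around [stats::wilcox.test] fixing the exactness policy:
#' exact enumeration when the pooled sample size is at most 12 and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return an object of class `"rank_sum_result"`: list with
#'   `statistic` (Mann-Whitney U for sample `a`), `p_value`, `n_a`,
#'   `n_b`, `alternative`, `exact`.
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  no_ties <- !any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 12) && no_ties
  wt <- stats::wilcox.test(a, b, alternative = alternative,
                           exact = exact, correct = TRUE)
  structure(list(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_a = length(a), n_b = length(b),
    alternative = alternative, exact = exact
  ), class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum: W = %g, p = %.4g (%s, n = %d vs %d, %s)\n",
    x$statistic, x$p_value, x$alternative, x$n_a, x$n_b,
    if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

# significance stars from p thresholds 0.05 / 0.01 / 0.001
.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Per-phylum trait contrasts
#'
#' For each trait and each pair of phyla, optionally standardizes rate
#' traits to a common temperature with [arrhenius_correct] (using each
#' isolate's thermal optimum as the observation temperature), then runs
#' [rank_sum_test] and tabulates group medians, sample sizes, p-values
#' and significance stars.  No multiple-testing correction is applied;
#' the number of tests run is recorded.
#'
#' @param table trait data.frame with a `phylum` column.
#' @param traits trait columns to contrast.
#' @param correct_traits subset of `traits` to Arrhenius-correct
#'   (must be positive rates); empty for no correction.
#' @param temp_column column holding each isolate's observation
#'   temperature (degC) for the correction.
#' @param t_target target temperature, degC.
#' @param E activation energy for the correction, eV. `E = 0` leaves
#'   rates unchanged.
#' @param alternative passed to [rank_sum_test].
#' @return an object of class `"phylum_summary"`: data.frame with one
#'   row per (trait, phylum pair): `trait`, `phylum_a`, `phylum_b`,
#'   `median_a`, `median_b`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `stars`; attribute `n_tests`.
#' @export
phylum_summary <- function(table,
                           traits = c("mu_max", "r_max", "log_atp",
                                      "carrying_capacity"),
                           correct_traits = character(),
                           temp_column = "topt",
                           t_target = 20, E = 0.61,
                           alternative = "two.sided") {
  if (!"phylum" %in% names(table)) stop("table must have a phylum column")
  phyla <- sort(unique(stats::na.omit(table$phylum)))
  if (length(phyla) < 2) stop("at least 2 phyla are required")
  traits <- intersect(traits, names(table))
  if (!length(traits)) stop("no requested trait columns present")
  work <- table
  for (tr in intersect(correct_traits, traits)) {
    work[[tr]] <- arrhenius_correct(work[[tr]], work[[temp_column]],
                                    t_target = t_target, E = E)
  }
  pairs <- utils::combn(phyla, 2, simplify = FALSE)
  rows <- list()
  for (tr in traits) {
    for (pr in pairs) {
      va <- work[[tr]][work$phylum == pr[1]]
      vb <- work[[tr]][work$phylum == pr[2]]
      rs <- rank_sum_test(va, vb, alternative = alternative)
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, phylum_a = pr[1], phylum_b = pr[2],
        median_a = stats::median(va, na.rm = TRUE),
        median_b = stats::median(vb, na.rm = TRUE),
        n_a = rs$n_a, n_b = rs$n_b,
        statistic = rs$statistic, p_value = rs$p_value,
        stars = .stars(rs$p_value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("phylum_summary", class(out))
  out
}
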