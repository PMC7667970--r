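#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `homa_ir(G, I) = G * I / 22.5` with fasting glucose in mM and fasting
#' insulin in microunits per millilitre — the standard normalisation so that
#' a healthy reference subject scores about 1. Bilinear in both arguments.
#'
#' @param glucose_mM Fasting glucose, mM (> 0). Vectorised.
#' @param insulin_uU_ml Fasting insulin, µU/ml (> 0). Vectorised.
#' @return HOMA-IR (dimensionless).
#' @examples
#' homa_ir(5, 9)   # 2
#' @export
homa_ir <- function(glucose_mM, insulin_uU_ml) {
  if (any(!is.finite(glucose_mM)) || any(glucose_mM <= 0) ||
      any(!is.finite(insulin_uU_ml)) || any(insulin_uU_ml <= 0)) {
    abort_data("glucose and insulin must be positive to compute HOMA-IR")
  }
  glucose_mM * insulin_uU_ml / 22.5
}

#' Convert an insulin mass concentration to microunits per millilitre
#'
#' ELISA readouts are often reported in ng/ml; HOMA-IR uses µU/ml. The
#' default conversion factor 28.8 µU per ng corresponds to the WHO insulin
#' standard and can be overridden for assay-specific calibrations.
#'
#' @param ng_ml Insulin in ng/ml.
#' @param factor µU per ng (default 28.8).
#' @return Insulin in µU/ml.
#' @export
insulin_to_uU_ml <- function(ng_ml, factor = 28.8) {
  ng_ml * factor
}

#' Label a mouse diabetic from its postprandial glucose
#'
#' Diabetes is called when postprandial blood glucose strictly exceeds
#' 14.5 mM (the screening threshold used for non-obese diabetic mice).
#'
#' @param postprandial_glucose_mM Postprandial glucose, mM. Vectorised.
#' @param threshold_mM Threshold, default 14.5 mM.
#' @return Logical: `TRUE` if diabetic.
#' @examples
#' label_diabetic(c(8, 14.5, 14.6))
#' @export
label_diabetic <- function(postprandial_glucose_mM, threshold_mM = 14.5) {
  if (any(!is.finite(postprandial_glucose_mM)) || any(postprandial_glucose_mM <= 0)) {
    abort_data("glucose must be positive")
  }
  postprandial_glucose_mM > threshold_mM
}

#' Two-sided Mann-Whitney U test
#'
#' Nonparametric two-group comparison. Uses the exact null distribution of U
#' when the combined sample size is at most 14 and there are no ties, and the
#' tie-corrected normal approximation (with continuity correction) otherwise;
#' the `method` field records which path ran. If every value in both groups
#' is identical the test is degenerate and `p = 1` is returned with a
#' warning.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A one-row tibble: `method`, `statistic` (U of the first sample),
#'   `p_value`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort_data("each sample needs at least 2 values")
  if (any(!is.finite(c(a, b)))) abort_data("samples must be finite")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical in both groups: Mann-Whitney test is degenerate, p = 1")
    return(tibble::tibble(
      method = "mann_whitney_degenerate",
      statistic = length(a) * length(b) / 2,
      p_value = 1,
      n1 = length(a), n2 = length(b)
    ))
  }
  tie_free <- !anyDuplicated(c(a, b))
  if (tie_free && length(a) + length(b) <= 14) {
    wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    method <- "mann_whitney_exact"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    method <- "mann_whitney_normal_approx"
  }
  tibble::tibble(
    method = method,
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n1 = length(a), n2 = length(b)
  )
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-corrected z-scores of skewness (D'Agostino) and
#' kurtosis (Anscombe-Glynn) into `K^2 = z_skew^2 + z_kurt^2`, referred to a
#' chi-square distribution with 2 degrees of freedom. The test is undefined
#' below n = 8; such samples are reported as `normal = FALSE` with an
#' `insufficient n` note so that downstream gating falls back to
#' nonparametric methods, as is appropriate for small animal groups.
#'
#' @param x Numeric sample.
#' @param alpha Significance level for the `normal` flag (default 0.05).
#' @return A one-row tibble: `method`, `statistic` (K^2), `p_value`,
#'   `normal`, `n`, `note`.
#' @export
normality_test <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  insufficient <- function(note) tibble::tibble(
    method = "dagostino_pearson", statistic = NA_real_, p_value = NA_real_,
    normal = FALSE, n = n, note = note
  )
  if (n < 8) return(insufficient("insufficient n (< 8): treated as non-normal"))
  if (stats::sd(x) == 0) return(insufficient("zero variance: normality undefined"))

  m <- x - mean(x)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)

  # skewness z (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha_s <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1
  z_skew <- delta * log(y / alpha_s + sqrt((y / alpha_s)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  tibble::tibble(
    method = "dagostino_pearson", statistic = k2, p_value = p,
    normal = p > alpha, n = n, note = NA_character_
  )
}

#' Normality-gated correlation with conditional regression line
#'
#' Correlates two paired variables the way the cohort figures do: both
#' variables are screened with the D'Agostino-Pearson normality test; if both
#' pass, the Pearson coefficient is computed, otherwise the nonparametric
#' Spearman coefficient. A least-squares regression line is fitted and
#' reported only when the correlation is significant (`p <= 0.05`),
#' mirroring the convention that a drawn regression line indicates a
#' significant correlation.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of the two variables.
#' @param alpha Significance level for both the normality gate and the
#'   regression-line rule (default 0.05).
#' @return A one-row tibble: `x`, `y`, `method`, `estimate` (r or rho),
#'   `p_value`, `normal_x`, `normal_y`, `slope`, `intercept` (NA unless the
#'   correlation is significant), `n`.
#' @examples
#' d <- data.frame(a = 1:20, b = 2 * (1:20) + 1)
#' correlate(d, "a", "b")
#' @export
correlate <- function(data, x, y, alpha = 0.05) {
  if (!all(c(x, y) %in% names(data))) {
    abort_data("`x` and `y` must name columns of `data`")
  }
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) abort_data("at least 3 complete pairs are required")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    abort_data("zero variance in one of the variables: correlation undefined")
  }
  nx <- normality_test(xv, alpha = alpha)
  ny <- normality_test(yv, alpha = alpha)
  if (nx$normal && ny$normal) {
    ct <- stats::cor.test(xv, yv, method = "pearson")
    method <- "pearson"
  } else {
    ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman"))
    method <- "spearman"
  }
  slope <- intercept <- NA_real_
  if (is.finite(ct$p.value) && ct$p.value <= alpha) {
    fit <- stats::lm(yv ~ xv)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  tibble::tibble(
    x = x, y = y, method = method,
    estimate = unname(ct$estimate), p_value = ct$p.value,
    normal_x = nx$normal, normal_y = ny$normal,
    slope = slope, intercept = intercept, n = n
  )
}

#' Two-group comparison with a normality gate
#'
#' Compares one variable between exactly two groups, dispatching to the
#' classical unpaired (equal-variance) t test when both groups pass the
#' D'Agostino-Pearson normality screen and to the Mann-Whitney U test
#' otherwise — small groups (n < 8), for which the normality test is
#' undefined, therefore always take the nonparametric path. Group means and
#' standard deviations are reported alongside the test.
#'
#' @param data A data frame.
#' @param variable Column name (string) of the variable to compare.
#' @param group Column name (string) of the grouping factor; it must have
#'   exactly two levels present in `data`.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return A one-row tibble: `variable`, `group1`, `group2`, `n1`, `n2`,
#'   `mean1`, `sd1`, `mean2`, `sd2`, `method`, `statistic`, `p_value`.
#' @examples
#' d <- data.frame(g = rep(c("lean", "ob"), each = 6),
#'                 v = c(1:6, 11:16))
#' compare_groups(d, "v", "g")
#' @export
compare_groups <- function(data, variable, group, alpha = 0.05) {
  if (!all(c(variable, group) %in% names(data))) {
    abort_data("`variable` and `group` must name columns of `data`")
  }
  g <- as.character(data[[group]])
  v <- data[[variable]]
  ok <- is.finite(v) & !is.na(g)
  g <- g[ok]; v <- v[ok]
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    abort_data(sprintf(
      "`%s` has %d groups; exactly two are required (compare pairs of groups separately)",
      group, length(levels)
    ))
  }
  a <- v[g == levels[1]]
  b <- v[g == levels[2]]
  if (length(a) < 2 || length(b) < 2) abort_data("each group needs at least 2 values")

  both_normal <- isTRUE(normality_test(a, alpha)$normal) &&
    isTRUE(normality_test(b, alpha)$normal)
  if (length(unique(c(a, b))) == 1L) {
    res <- suppressWarnings(mann_whitney(a, b))
  } else if (both_normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- tibble::tibble(method = "t_test",
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value)
  } else {
    res <- mann_whitney(a, b)
  }
  tibble::tibble(
    variable = variable,
    group1 = levels[1], group2 = levels[2],
    n1 = length(a), n2 = length(b),
    mean1 = mean(a), sd1 = stats::sd(a),
    mean2 = mean(b), sd2 = stats::sd(b),
    method = res$method, statistic = res$statistic, p_value = res$p_value
  )
}
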