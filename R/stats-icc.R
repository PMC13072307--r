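#' Two-way random-effects absolute-agreement ICC
#'
#' Reliability of the opacity measurement across raters. The table is
#' decomposed by two-way ANOVA (rows = subjects, columns = raters) into
#' between-subject, between-rater and residual mean squares, from which the
#' single-measures and average-measures absolute-agreement intraclass
#' correlations are estimated, with F-based 95% confidence intervals
#' (McGraw & Wong). "Absolute agreement" charges systematic rater offsets
#' against reliability, unlike the consistency definition. The reported F
#' test (`MS_subjects / MS_error`, df `n-1` and `(n-1)(k-1)`) tests ICC = 0.
#'
#' @param table A [rating_table()] (complete `n x k`, `n, k >= 2`).
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return An `icc_result` with `icc_single`, `icc_average`, `ci95_single`,
#'   `ci95_average`, `f_value`, `df1`, `df2`, `p_value`, `model_tag`.
#' @export
icc_two_way_random_absolute <- function(table, conf_level = 0.95) {
  x <- unclass(as.matrix(table))
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop_ovm("ICC needs at least 2 subjects and 2 raters")
  if (anyNA(x)) stop_ovm("ICC table must be complete")

  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- max(0, ss_err) / ((n - 1) * (k - 1))

  if (ms_r == 0 && ms_e == 0)
    stop_ovm("zero subject and error variance: ICC undefined")

  icc_s <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  icc_a <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)

  alpha <- 1 - conf_level
  # Satterthwaite df of the denominator (McGraw & Wong); closed limits where
  # MS_e = 0 would make F_j = MS_c / MS_e indeterminate.
  if (ms_e > 0) {
    fj <- ms_c / ms_e
    a <- k * icc_s * fj + n * (1 + (k - 1) * icc_s) - k * icc_s
    v <- ((k - 1) * (n - 1) * a^2) /
      ((n - 1) * k^2 * icc_s^2 * fj^2 + (n * (1 + (k - 1) * icc_s) - k * icc_s)^2)
  } else {
    v <- if (ms_c > 0) (k - 1) * (n - 1) else Inf
  }
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms_r - fl * ms_e) / (fl * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
  hi <- n * (fu * ms_r - ms_e) / (k * ms_c + (k * n - k - n) * ms_e + n * fu * ms_r)

  f_value <- if (ms_e > 0) ms_r / ms_e else Inf
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- pf(f_value, df1, df2, lower.tail = FALSE)

  structure(
    list(icc_single = icc_s,
         icc_average = icc_a,
         ci95_single = c(lo, hi),
         ci95_average = c(spearman_brown(lo, k), spearman_brown(hi, k)),
         f_value = f_value, df1 = df1, df2 = df2, p_value = p,
         n_subjects = n, n_raters = k,
         ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
         conf_level = conf_level,
         model_tag = "two-way random, absolute agreement"),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s (n = %d subjects, k = %d raters)\n",
              x$model_tag, x$n_subjects, x$n_raters))
  cat(sprintf("  Single Measures  %.3f  %d%% CI [%.3f, %.3f]\n",
              x$icc_single, round(100 * x$conf_level),
              x$ci95_single[1], x$ci95_single[2]))
  cat(sprintf("  Average Measures %.3f  %d%% CI [%.3f, %.3f]\n",
              x$icc_average, round(100 * x$conf_level),
              x$ci95_average[1], x$ci95_average[2]))
  cat(sprintf("  F = %.4g on (%d, %d) df, p = %.3g  [%s agreement]\n",
              x$f_value, x$df1, x$df2, x$p_value, interpret_icc(x$icc_single)))
  invisible(x)
}

#' Spearman-Brown aggregation of a single-measures ICC
#'
#' Relates the reliability of one rating to the reliability of the mean of
#' `k` ratings: `k * r / (1 + (k - 1) * r)`. This is the step connecting the
#' "Single Measures" and "Average Measures" rows of a reliability table.
#'
#' @param icc_single Single-measures ICC in (-1, 1].
#' @param k Number of aggregated measurements (>= 1).
#' @return The average-measures (k-measure) ICC.
#' @export
spearman_brown <- function(icc_single, k) {
  stopifnot(is.numeric(icc_single), is.numeric(k), all(k >= 1))
  if (any(icc_single <= -1 | icc_single > 1))
    stop_ovm("icc_single must lie in (-1, 1]")
  k * icc_single / (1 + (k - 1) * icc_single)
}

#' Qualitative interpretation of an ICC value
#'
#' Cutpoints: below 0.5 poor, 0.5 to below 0.75 fair, 0.75 to 0.9 good,
#' above 0.9 excellent (boundaries 0.5 and 0.75 fall upward, 0.9 is still
#' "good").
#'
#' @param value ICC in `[-1, 1]`.
#' @return One of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(value) {
  stopifnot(is_scalar_num(value), value >= -1, value <= 1)
  if (value > 0.9) "excellent"
  else if (value >= 0.75) "good"
  else if (value >= 0.5) "fair"
  else "poor"
}
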