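#' Coefficient of variation
#'
#' Sample SD (n-1 denominator) over the mean, as a percentage; the
#' consistency metric used to compare scar severity across injury schedules.
#'
#' @param values Numeric vector, `n >= 2`, positive mean.
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop_ovm("CoV needs at least 2 values")
  m <- mean(values)
  if (m <= 0) stop_ovm("CoV undefined: mean is %g (must be > 0)", m)
  100 * sd(values) / m
}

#' Longitudinal per-eye opacity series
#'
#' @param eye_id Eye identifier.
#' @param timepoints Strictly increasing numeric timepoints (weeks).
#' @param percents Percent opacity at each timepoint, in `[0, 100]`.
#' @param group Treatment arm label.
#' @return A `longitudinal_series`.
#' @export
longitudinal_series <- function(eye_id, timepoints, percents, group = NA_character_) {
  stopifnot(length(timepoints) == length(percents))
  if (length(timepoints) && any(diff(timepoints) <= 0))
    stop_ovm("timepoints must be strictly increasing")
  if (length(percents) && (min(percents) < 0 || max(percents) > 100))
    stop_ovm("percents must lie in [0, 100]")
  structure(list(eye_id = as.character(eye_id), timepoints = timepoints,
                 percents = percents, group = as.character(group)),
            class = "longitudinal_series")
}

#' Weekly percentage change of opacity volume
#'
#' For each consecutive timepoint pair, `100 * (v[t+1] - v[t]) / v[t]`;
#' negative values are reductions.
#'
#' @param series A [longitudinal_series()] or a numeric vector of ordered
#'   values.
#' @return Numeric vector of per-interval percent changes (length one less
#'   than the series).
#' @export
weekly_change <- function(series) {
  v <- if (inherits(series, "longitudinal_series")) series$percents else series
  stopifnot(is.numeric(v))
  if (length(v) < 2L) stop_ovm("weekly change needs at least 2 timepoints")
  base <- v[-length(v)]
  if (any(base == 0))
    stop_ovm("zero baseline at interval(s) %s: percent change undefined",
             paste(which(base == 0), collapse = ", "))
  100 * diff(v) / base
}

#' Select eyes exceeding the opacity eligibility threshold
#'
#' Keeps eyes whose pre-treatment percent opacity exceeds the pre-injury
#' baseline by strictly more than `min_percent` points (the "greater than
#' 5% opacity" entry rule). Eyes without a baseline row are excluded with a
#' warning.
#'
#' @param measurements Data frame with columns `eye_id`, `timepoint`,
#'   `percent_opacity` (as written by [write_measurements()]).
#' @param min_percent Eligibility threshold in percentage points.
#' @param baseline_label,pre_label `timepoint` labels of the pre-injury
#'   baseline and the pre-treatment scan.
#' @return The rows of `measurements` belonging to eligible eyes.
#' @export
filter_eligible <- function(measurements, min_percent = 5,
                            baseline_label = "baseline",
                            pre_label = "pre_treatment") {
  stopifnot(is.data.frame(measurements),
            all(c("eye_id", "timepoint", "percent_opacity") %in%
                  names(measurements)))
  eyes <- unique(measurements$eye_id)
  keep <- character(0)
  for (eye in eyes) {
    rows <- measurements[measurements$eye_id == eye, ]
    b <- rows$percent_opacity[rows$timepoint == baseline_label]
    p <- rows$percent_opacity[rows$timepoint == pre_label]
    if (!length(b)) {
      warn_ovm("eye '%s' has no '%s' measurement; excluded", eye, baseline_label)
      next
    }
    if (!length(p)) {
      warn_ovm("eye '%s' has no '%s' measurement; excluded", eye, pre_label)
      next
    }
    if (p[1] - b[1] > min_percent) keep <- c(keep, eye)
  }
  measurements[measurements$eye_id %in% keep, , drop = FALSE]
}

#' Mann-Whitney U test
#'
#' Exact p-value by enumeration of rank assignments when both groups have at
#' most `exact_max` observations (default 8), otherwise the normal
#' approximation with tie-corrected variance. Two-sided.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param exact_max Per-group size limit for the exact route.
#' @return `list(U, p_value, method)`; `U` counts pairs where `a` precedes
#'   `b` (so swapping the samples maps `U` to `n_a * n_b - U`).
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (!length(a) || !length(b)) stop_ovm("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    # enumerate all C(n, na) assignments of the observed (mid-)ranks
    sets <- combn(n, na)
    us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
    list(U = u, p_value = min(1, p), method = "mann-whitney exact")
  } else {
    ties <- table(r)
    mu <- na * nb / 2
    v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (v <= 0) 1 else 2 * pnorm(-abs(u - mu) / sqrt(v))
    list(U = u, p_value = min(1, p), method = "mann-whitney normal approximation")
  }
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across three or more groups, followed by
#' Dunn z-statistics for every pair with Bonferroni-adjusted p-values. With
#' exactly two groups the comparison delegates to [mann_whitney()].
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return A `group_comparison`: omnibus `statistic`, `df`, `p_value`,
#'   `method`, and a `pairwise` data frame (empty for the two-group case).
#' @export
compare_groups_kw_dunn <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- sprintf("group%d", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop_ovm("group(s) %s have fewer than 2 observations",
             paste(names(groups)[sizes < 2L], collapse = ", "))
  g <- length(groups)
  if (g == 2L) {
    mw <- mann_whitney(groups[[1]], groups[[2]])
    return(structure(list(statistic = mw$U, df = NA_integer_,
                          p_value = mw$p_value, method = mw$method,
                          pairwise = data.frame()),
                     class = "group_comparison"))
  }
  x <- unlist(groups, use.names = FALSE)
  lab <- rep(names(groups), sizes)
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, lab, mean)[names(groups)]
  ties <- table(r)
  tie_sum <- sum(ties^3 - ties)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  corr <- 1 - tie_sum / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  p <- pchisq(h, df = g - 1, lower.tail = FALSE)

  pairs <- combn(names(groups), 2)
  sigma2 <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = NA_real_, p_unadjusted = NA_real_, p_adjusted = NA_real_,
                   stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / sizes[[i1]] + 1 / sizes[[i2]]))
    z <- if (se > 0) (rbar[[i1]] - rbar[[i2]]) / se else 0
    pw$z[j] <- z
    pw$p_unadjusted[j] <- 2 * pnorm(-abs(z))
    pw$p_adjusted[j] <- min(1, 2 * pnorm(-abs(z)) * m)
  }
  structure(list(statistic = h, df = g - 1L, p_value = p,
                 method = "kruskal-wallis + dunn (bonferroni)",
                 pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$method))
  if (is.na(x$df))
    cat(sprintf("  U = %g, p = %.4g\n", x$statistic, x$p_value))
  else
    cat(sprintf("  H = %.4g on %d df, p = %.4g\n", x$statistic, x$df, x$p_value))
  if (nrow(x$pairwise)) {
    cat("  pairwise (Dunn, Bonferroni-adjusted):\n")
    for (j in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s vs %s: z = %.3f, p = %.4g\n",
                  x$pairwise$group1[j], x$pairwise$group2[j],
                  x$pairwise$z[j], x$pairwise$p_adjusted[j]))
  }
  invisible(x)
}

#' Sample size per group
#'
#' The printed power formula `n = 1 + 2 C (s / d)^2`, rounded up to the next
#' whole animal: `C` is the constant for the chosen significance and power
#' (10.51 at alpha 0.05, power 0.8), `s` the SD and `d` the effect size.
#'
#' @param effect_d Effect size (> 0), same units as `sd_s`.
#' @param sd_s Standard deviation (>= 0).
#' @param C Power constant.
#' @return Integer group size.
#' @export
sample_size <- function(effect_d, sd_s, C = 10.51) {
  if (!is_scalar_num(effect_d) || effect_d <= 0)
    stop_ovm("effect size d must be > 0")
  if (!is_scalar_num(sd_s) || sd_s < 0) stop_ovm("sd s must be >= 0")
  if (!is_scalar_num(C) || C <= 0) stop_ovm("C must be > 0")
  as.integer(ceiling(1 + 2 * C * (sd_s / effect_d)^2))
}
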