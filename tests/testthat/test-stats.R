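test_that("ICC matches an independent reference implementation", {
  # expected values frozen from pingouin.intraclass_corr (ICC(A,1)/ICC(A,k))
  # on this exact table
  tab <- generate_rating_table(rating_spec(n_subjects = 12, n_raters = 2,
                                           subject_sd = 4, rater_sd = 0.8,
                                           error_sd = 1.2, grand_mean = 12,
                                           seed = 99))
  r <- icc_two_way_random_absolute(tab)
  expect_equal(r$icc_single, 0.5700351858, tolerance = 1e-9)
  expect_equal(r$icc_average, 0.7261431986, tolerance = 1e-9)
  expect_equal(r$f_value, 7.34253178, tolerance = 1e-7)
  expect_equal(r$p_value, 1.2782457050e-03, tolerance = 1e-8)
  expect_equal(round(r$ci95_single, 2), c(-0.09, 0.87))
  expect_equal(round(r$ci95_average, 2), c(-0.20, 0.93))
  expect_identical(r$model_tag, "two-way random, absolute agreement")
})

test_that("perfect agreement and degenerate tables", {
  vals <- cbind(c(3, 7, 11, 20), c(3, 7, 11, 20))
  r <- icc_two_way_random_absolute(rating_table(vals))
  expect_equal(r$icc_single, 1)
  expect_equal(r$icc_average, 1)
  expect_equal(r$ci95_single, c(1, 1))
  expect_error(icc_two_way_random_absolute(rating_table(matrix(5, 3, 2))),
               "undefined")
})

test_that("average-measures ICC equals the aggregation formula", {
  for (seed in 1:20) {
    k <- 2L + seed %% 3L
    tab <- generate_rating_table(rating_spec(n_subjects = 15, n_raters = k,
                                             subject_sd = 2 + seed %% 4,
                                             rater_sd = 0.5, error_sd = 1,
                                             seed = seed))
    r <- icc_two_way_random_absolute(tab)
    expect_equal(r$icc_average, spearman_brown(r$icc_single, k),
                 tolerance = 1e-10)
    if (r$icc_single >= 0) expect_gte(r$icc_average, r$icc_single)
  }
})

test_that("spearman_brown and interpretation cutpoints", {
  expect_equal(round(spearman_brown(0.998, 2), 3), 0.999)
  expect_equal(round(spearman_brown(0.994, 2), 3), 0.997)
  expect_equal(round(spearman_brown(1.000, 2), 2), 1.00)
  expect_equal(spearman_brown(0.42, 1), 0.42)
  expect_error(spearman_brown(-1, 2), "lie in")

  expect_identical(interpret_icc(0.999), "excellent")
  expect_identical(interpret_icc(0.9), "good")
  expect_identical(interpret_icc(0.75), "good")
  expect_identical(interpret_icc(0.5), "fair")
  expect_identical(interpret_icc(0.49), "poor")
})

test_that("coefficient of variation", {
  expect_equal(coefficient_of_variation(c(4, 4, 4)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)  # SD 1, mean 2
  v <- c(2.5, 8, 13, 4)
  expect_equal(coefficient_of_variation(v * 7), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-3, 1)), "mean")
  expect_error(coefficient_of_variation(5), "at least 2")
})

test_that("weekly change arithmetic", {
  expect_equal(weekly_change(c(10, 9, 8)), c(-10, -100 / 9))
  expect_equal(weekly_change(c(7, 7, 7, 7)), c(0, 0, 0))
  growth <- 20 * 1.097^(0:4)   # constant +9.7%/week geometric series
  expect_equal(weekly_change(growth), rep(9.7, 4), tolerance = 1e-9)
  s <- longitudinal_series("eye1", 0:2, c(10, 12, 15), group = "ctrl")
  expect_equal(weekly_change(s), c(20, 25))
  expect_error(weekly_change(c(0, 5)), "zero baseline")
  expect_error(longitudinal_series("e", c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("eligibility filter uses a strict 5-point threshold", {
  meas <- data.frame(
    eye_id = rep(c("a", "b", "c", "d"), each = 2),
    timepoint = rep(c("baseline", "pre_treatment"), 4),
    percent_opacity = c(1, 6.0,    # delta exactly 5: excluded
                        1, 6.1,    # delta 5.1: included
                        2, 2.5,    # naive-like: excluded
                        0, 20))    # clearly scarred: included
  out <- filter_eligible(meas)
  expect_setequal(unique(out$eye_id), c("b", "d"))

  missing <- data.frame(eye_id = c("e", "e"), timepoint = c("w1", "pre_treatment"),
                        percent_opacity = c(1, 30))
  expect_warning(out2 <- filter_eligible(missing), "no 'baseline'")
  expect_equal(nrow(out2), 0L)

  naive <- data.frame(eye_id = rep("f", 2),
                      timepoint = c("baseline", "pre_treatment"),
                      percent_opacity = c(0.4, 0.6))
  expect_equal(nrow(filter_eligible(naive)), 0L)
})

test_that("Mann-Whitney exact route matches enumeration and base R", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.100)  # 2 * P(U <= 0) = 2/20, by enumeration
  expect_match(r$method, "exact")

  # against the exact Wilcoxon distribution in base R (no ties)
  set.seed(7)
  a <- sample(1:100, 6); b <- sample(101:200, 7) - 120
  mine <- mann_whitney(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  # identical samples: symmetric distribution, p capped at 1
  same <- mann_whitney(c(5, 5, 6), c(5, 6, 5))
  expect_equal(same$p_value, 1)

  # swapping the samples reflects U
  expect_equal(mann_whitney(b, a)$U, length(a) * length(b) - mine$U)
})

test_that("Mann-Whitney normal approximation matches base R with ties", {
  set.seed(11)
  a <- sample(1:8, 12, TRUE); b <- sample(3:10, 15, TRUE)
  mine <- mann_whitney(a, b)
  expect_match(mine$method, "approximation")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis H matches base R and is rank-invariant", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(11, 12, 13, 14, 15),
            c = c(21, 22, 23, 24, 25))
  r <- compare_groups_kw_dunn(g)
  ref <- stats::kruskal.test(unlist(g), factor(rep(names(g), lengths(g))))
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)

  # monotone transform leaves ranks, hence H, unchanged
  r2 <- compare_groups_kw_dunn(lapply(g, function(v) exp(v / 5)))
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)

  # ties: still identical to base R
  set.seed(3)
  gt <- list(x = sample(1:4, 8, TRUE), y = sample(2:6, 9, TRUE),
             z = sample(1:6, 7, TRUE))
  rt <- compare_groups_kw_dunn(gt)
  reft <- stats::kruskal.test(unlist(gt), factor(rep(names(gt), lengths(gt))))
  expect_equal(rt$statistic, unname(reft$statistic), tolerance = 1e-12)

  ident <- list(a = c(2, 2), b = c(2, 2), c = c(2, 2))
  ri <- compare_groups_kw_dunn(ident)
  expect_equal(ri$statistic, 0)
  expect_equal(ri$p_value, 1)

  expect_error(compare_groups_kw_dunn(list(a = 1, b = c(1, 2), c = c(1, 2))),
               "fewer than 2")
})

test_that("Dunn standard errors match a permutation oracle", {
  set.seed(21)
  g <- list(a = rnorm(8), b = rnorm(10), c = round(rnorm(9), 1))
  r <- compare_groups_kw_dunn(g)
  expect_equal(nrow(r$pairwise), 3L)
  x <- unlist(g); lab <- rep(names(g), lengths(g))
  rk <- rank(x)
  diffs <- replicate(4000, {
    p <- sample(lab)
    mean(rk[p == "a"]) - mean(rk[p == "b"])
  })
  sizes <- lengths(g); n <- length(x)
  ties <- table(rk)
  se_analytic <- sqrt((n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))) *
                        (1 / sizes[["a"]] + 1 / sizes[["b"]]))
  expect_lt(abs(sd(diffs) - se_analytic) / se_analytic, 0.05)
  # and the reported z uses that SE
  ab <- r$pairwise[r$pairwise$group1 == "a" & r$pairwise$group2 == "b", ]
  expect_equal(ab$z, (mean(rk[lab == "a"]) - mean(rk[lab == "b"])) / se_analytic,
               tolerance = 1e-12)
  expect_equal(ab$p_adjusted, min(1, ab$p_unadjusted * 3), tolerance = 1e-12)
})

test_that("two groups delegate to Mann-Whitney; five give ten pairs", {
  two <- compare_groups_kw_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_match(two$method, "mann-whitney")
  expect_equal(two$p_value, 0.1)

  set.seed(5)
  five <- compare_groups_kw_dunn(setNames(
    lapply(1:5, function(i) rnorm(4, i)), letters[1:5]))
  expect_equal(nrow(five$pairwise), choose(5, 2))
})

test_that("sample size formula", {
  expect_equal(sample_size(30, 20), 11)        # ceil(1 + 2*10.51*(20/30)^2)
  expect_equal(sample_size(30, 30), 23)        # s = d: ceil(22.02)
  expect_equal(sample_size(30, 0), 1)          # s/d -> 0
  expect_error(sample_size(0, 10), "> 0")
  expect_error(sample_size(-2, 10), "> 0")
})
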