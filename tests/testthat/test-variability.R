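test_that("coefficient of variation matches the formula and its bands", {
  expect_equal(coefficient_of_variation(c(8, 10, 12)), 20)
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  set.seed(3)
  v <- stats::rlnorm(10000, 1, 0.4)
  expect_equal(coefficient_of_variation(v), 100 * stats::sd(v) / mean(v),
               tolerance = 1e-9)
  expect_equal(cv_band(c(7.7, 20, 121.8, 9.999, 10, 35, 35.001)),
               c("low", "acceptable", "high", "low", "acceptable",
                 "acceptable", "high"))
})

test_that("the CV radar table bands every stratum consistently", {
  tab <- simulate_feature_table(study_design("paper"), seed = 5)
  radar <- cv_radar_table(tab)
  expect_equal(nrow(radar), 10 * nrow(unique(tab[, c("subpopulation",
                                                     "condition")])))
  ok <- !radar$missing
  expect_identical(radar$band[ok], cv_band(radar$cv_percent[ok]))
  expect_true(all(radar$cv_percent[ok] >= 0))
})

test_that("two-group comparison reproduces the pooled t and its tail maths", {
  r <- compare_two_groups(c(1, 3), c(2, 2), tail = "greater")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)
  r2 <- compare_two_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$statistic, -3 * sqrt(3 / 2), tolerance = 1e-12)  # diff -3, pooled sd 1, se sqrt(2/3)
  expect_equal(r2$df, 4)
  expect_equal(r2$p_value, 2 * t_tail_numeric(abs(r2$statistic), 4),
               tolerance = 1e-8)
  # degenerate pooled variance
  expect_equal(compare_two_groups(c(2, 2), c(2, 2))$p_value, 1)
  deg <- compare_two_groups(c(2, 2), c(3, 3))
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)
})

test_that("type-I error of the one-sided t test is near nominal", {
  set.seed(10)
  rej <- replicate(1000, {
    a <- stats::rnorm(8)
    b <- stats::rnorm(8)
    compare_two_groups(a, b, tail = "less")$p_value <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("F = t^2 on every two-group dataset", {
  set.seed(11)
  for (i in 1:50) {
    a <- stats::rnorm(4 + i %% 5)
    b <- stats::rnorm(3 + i %% 4, mean = 0.5)
    tt <- compare_two_groups(a, b)
    ff <- one_way_anova_tukey(list(a = a, b = b))
    expect_lt(abs(ff$anova$statistic - tt$statistic^2),
              1e-9 * max(1, tt$statistic^2))
  }
})

test_that("one-way ANOVA matches a brute-force sum-of-squares oracle", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  res <- one_way_anova_tukey(groups)
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, 0))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), 0))
  f_oracle <- (ss_between / 2) / (ss_within / 6)
  expect_equal(res$anova$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(nrow(res$tukey), 3L)
  ident <- one_way_anova_tukey(list(a = c(1, 1), b = c(1, 1)))
  expect_true(ident$anova$degenerate)
})

test_that("stars map p values monotonically into the printed bands", {
  p <- c(5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 0.04, 0.05, 0.06, 0.5)
  s <- significance_stars(p)
  expect_equal(s, c("****", "****", "***", "***", "**", "*", "*", "ns", "ns"))
  expect_true(all(diff(match(s, c("****", "***", "**", "*", "ns"))) >= 0))
})

test_that("two-way Sholl ANOVA: identical groups give capped adjusted p", {
  set.seed(12)
  m <- matrix(stats::rpois(15 * 6, 8), 15, 6)
  res <- sholl_two_way_anova(list(control = m, TBI = m), radii = seq(2, 12, 2))
  expect_true(all(res$contrasts$p_adjusted == 1))
  expect_true(all(res$contrasts$stars == "ns"))
  expect_error(sholl_two_way_anova(list(a = m, b = m[, 1:4]),
                                   radii = seq(2, 12, 2)), "re-bin")
})

test_that("two-way Sholl ANOVA localizes a window shift with Bonferroni", {
  set.seed(13)
  radii <- seq(4, 40, 4)
  hits <- 0L
  for (rep in 1:10) {
    base <- matrix(stats::rnorm(15 * 10, 10, 1), 15, 10)
    shifted <- matrix(stats::rnorm(15 * 10, 10, 1), 15, 10)
    window <- radii >= 16 & radii <= 28
    shifted[, window] <- shifted[, window] + 3
    res <- sholl_two_way_anova(list(control = base, TBI = shifted), radii)
    sig <- res$contrasts$p_adjusted <= 0.05
    if (all(sig[window]) && !any(sig[!window])) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("two-way main-effect F matches a hand-computed balanced SS oracle", {
  set.seed(14)
  radii <- c(2, 4, 6)
  g1 <- matrix(stats::rnorm(4 * 3, mean = 5), 4, 3)   # 2 groups x 3 radii
  g2 <- matrix(stats::rnorm(4 * 3, mean = 6), 4, 3)
  res <- sholl_two_way_anova(list(a = g1, b = g2), radii)
  # balanced two-way decomposition from cell means, by hand
  n_cell <- 4
  cells <- rbind(colMeans(g1), colMeans(g2))       # group x radius means
  grand <- mean(cells)
  g_means <- rowMeans(cells)
  r_means <- colMeans(cells)
  ss_group <- n_cell * length(radii) * sum((g_means - grand)^2)
  ss_radius <- n_cell * 2 * sum((r_means - grand)^2)
  inter <- sweep(sweep(cells, 1, g_means), 2, r_means) + grand
  ss_inter <- n_cell * sum(inter^2)
  ss_resid <- sum(sweep(g1, 2, colMeans(g1))^2) +
    sum(sweep(g2, 2, colMeans(g2))^2)
  df_resid <- 2 * 3 * (n_cell - 1)
  an <- res$anova
  expect_equal(an$statistic[an$term == "group"],
               (ss_group / 1) / (ss_resid / df_resid), tolerance = 1e-9)
  expect_equal(an$statistic[an$term == "radius"],
               (ss_radius / 2) / (ss_resid / df_resid), tolerance = 1e-9)
  expect_equal(an$statistic[an$term == "group:radius"],
               (ss_inter / 2) / (ss_resid / df_resid), tolerance = 1e-9)
})

test_that("the significance screen recovers the designed effect pattern", {
  tab <- simulate_feature_table(study_design("significance"), seed = 77)
  res <- significance_screen(tab)
  sm <- res$summary
  lower <- sm$n_significant[sm$subpopulation == "protoplasmic_lower"]
  upper <- sm$n_significant[sm$subpopulation == "protoplasmic_upper"]
  expect_gte(lower, 8L)
  expect_lte(upper, 2L)
  # the null design stays near the nominal level
  tab0 <- simulate_feature_table(study_design("null"), seed = 78)
  sm0 <- significance_screen(tab0)$summary
  expect_lte(max(sm0$n_significant), 3L)
  # summary helper: all p = 1 means 0 of 10
  fake <- data.frame(subpopulation = "pial",
                     parameter = PARAMETER_NAMES, p_value = 1)
  expect_equal(significant_parameter_summary(fake)$n_significant, 0L)
})
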