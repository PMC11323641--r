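#' Coefficient of variation (percent)
#'
#' 100 times the sample standard deviation (n - 1 denominator) over the
#' mean. Requires n >= 2 and a nonzero mean.
#'
#' @param values Numeric vector.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Band a CV value
#'
#' `low` below 10%, `acceptable` from 10% to 35%, `high` above 35%.
#'
#' @param cv_percent Numeric vector of CV values (percent).
#' @return Character vector of bands.
#' @export
cv_band <- function(cv_percent) {
  ifelse(cv_percent < 10, "low",
         ifelse(cv_percent <= 35, "acceptable", "high"))
}

#' CV radar table across subpopulations and parameters
#'
#' One row per (subpopulation, condition, parameter) stratum with the CV
#' and its variability band. Strata with fewer than 2 cells are flagged
#' missing rather than dropped.
#'
#' @param table Validated feature table.
#' @return data.frame with `subpopulation`, `condition`, `parameter`,
#'   `n`, `cv_percent`, `band`, `missing`.
#' @export
cv_radar_table <- function(table) {
  table <- validate_feature_table(table)
  strata <- unique(table[, c("subpopulation", "condition")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sub <- table[table$subpopulation == strata$subpopulation[i] &
                   table$condition == strata$condition[i], , drop = FALSE]
    for (p in seq_along(PARAMETER_NAMES)) {
      v <- sub[[FEATURE_COLUMNS[p]]]
      ok <- length(v) >= 2L && mean(v) != 0
      cv <- if (ok) coefficient_of_variation(v) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        subpopulation = strata$subpopulation[i],
        condition = strata$condition[i],
        parameter = PARAMETER_NAMES[p],
        n = length(v),
        cv_percent = cv,
        band = if (ok) cv_band(cv) else NA_character_,
        missing = !ok,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Significance stars for a p value
#'
#' `****` for p <= 0.0001, `***` <= 0.001, `**` <= 0.01, `*` <= 0.05,
#' `ns` otherwise.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 1e-2, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Unpaired Student's t test between two groups
#'
#' Equal-variance (pooled) t statistic with df = n_a + n_b - 2. Degenerate
#' inputs (zero pooled variance) return p = 1 for equal means and p = 0
#' (flagged) for unequal means. Welch's correction is available by flag.
#'
#' @param values_a,values_b Numeric vectors, each n >= 2.
#' @param tail `"two.sided"`, `"less"` (mean a < mean b) or `"greater"`.
#' @param welch Use Welch's unequal-variance t instead (default FALSE).
#' @return data.frame with `statistic`, `df`, `p_value`, `stars`, `tail`,
#'   `degenerate`.
#' @export
compare_two_groups <- function(values_a, values_b, tail = "two.sided",
                               welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2")
  pooled_var <- (sum((values_a - mean(values_a))^2) +
                   sum((values_b - mean(values_b))^2)) /
    (length(values_a) + length(values_b) - 2L)
  degenerate <- FALSE
  if (pooled_var == 0) {
    degenerate <- mean(values_a) != mean(values_b)
    p <- if (degenerate) 0 else 1
    out <- data.frame(statistic = if (degenerate) Inf else 0,
                      df = length(values_a) + length(values_b) - 2L,
                      p_value = p, stars = significance_stars(p),
                      tail = tail, degenerate = degenerate,
                      stringsAsFactors = FALSE)
    return(out)
  }
  tt <- stats::t.test(values_a, values_b, alternative = tail,
                      var.equal = !welch)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, stars = significance_stars(tt$p.value),
             tail = tail, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `anova` (data.frame: statistic F, df1, df2, p_value,
#'   stars, degenerate) and `tukey` (data.frame of pairwise contrasts with
#'   adjusted p values).
#' @export
one_way_anova_tukey <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 1L))))
  degenerate <- stats::var(df$value) == 0
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  fstat <- an[["F value"]][1L]
  p <- an[["Pr(>F)"]][1L]
  if (degenerate) { fstat <- 0; p <- 1 }
  tk <- as.data.frame(stats::TukeyHSD(fit)$group)
  tukey <- data.frame(contrast = rownames(tk), diff = tk$diff,
                      p_adjusted = if (degenerate) rep(1, nrow(tk)) else tk$`p adj`,
                      stringsAsFactors = FALSE)
  tukey$stars <- significance_stars(tukey$p_adjusted)
  list(anova = data.frame(statistic = fstat, df1 = an$Df[1L], df2 = an$Df[2L],
                          p_value = p, stars = significance_stars(p),
                          degenerate = degenerate, stringsAsFactors = FALSE),
       tukey = tukey)
}

#' Two-way ANOVA on Sholl profiles with Bonferroni per-radius contrasts
#'
#' Factors are group and shell radius (profiles must share a common shell
#' grid). Per-radius group contrasts use the pooled residual variance of
#' the two-way fit and Bonferroni adjustment (alpha divided by the number
#' of radii, i.e. p multiplied by the radius count, capped at 1).
#'
#' @param profiles_by_group Named list (2 groups) of matrices, each cells x
#'   radii of intersection counts, sharing column order.
#' @param radii Numeric vector of shell radii (um), length = ncol.
#' @return List with `anova` (main effects and interaction) and
#'   `contrasts` (per-radius t contrasts with adjusted p and stars).
#' @export
sholl_two_way_anova <- function(profiles_by_group, radii) {
  if (length(profiles_by_group) != 2L) stop("exactly 2 groups are required")
  ncols <- vapply(profiles_by_group, ncol, 1L)
  if (length(unique(ncols)) != 1L || ncols[1L] != length(radii))
    stop("misaligned radii across groups: re-bin profiles to a common grid")
  gn <- names(profiles_by_group)
  long <- do.call(rbind, lapply(gn, function(g) {
    m <- profiles_by_group[[g]]
    data.frame(count = as.vector(m),
               radius = factor(rep(radii, each = nrow(m)), levels = radii),
               group = g)
  }))
  long$group <- factor(long$group, levels = gn)
  fit <- stats::aov(count ~ group * radius, data = long)
  an <- summary(fit)[[1L]]
  anova <- data.frame(term = trimws(rownames(an)), df = an$Df,
                      statistic = an$`F value`, p_value = an$`Pr(>F)`,
                      stringsAsFactors = FALSE)
  ms_resid <- an["Residuals", "Mean Sq"]
  df_resid <- an["Residuals", "Df"]
  n1 <- nrow(profiles_by_group[[1L]])
  n2 <- nrow(profiles_by_group[[2L]])
  se <- sqrt(ms_resid * (1 / n1 + 1 / n2))
  contrasts <- do.call(rbind, lapply(seq_along(radii), function(j) {
    d <- mean(profiles_by_group[[1L]][, j]) - mean(profiles_by_group[[2L]][, j])
    tstat <- if (se > 0) d / se else 0
    p <- 2 * stats::pt(-abs(tstat), df_resid)
    data.frame(radius = radii[j], diff = d, statistic = tstat,
               p_value = p, stringsAsFactors = FALSE)
  }))
  contrasts$p_adjusted <- pmin(contrasts$p_value * length(radii), 1)
  contrasts$stars <- significance_stars(contrasts$p_adjusted)
  list(anova = anova, contrasts = contrasts)
}

#' Per-subpopulation significance screen and summary
#'
#' For each subpopulation and each of the ten parameters, compares control
#' cells against reactive cells with an unpaired Student's t test. Within a
#' subpopulation whose TBI cells carry zone labels, the reactive group is
#' restricted to the contusion core (A1), where reactivity is defined;
#' subpopulations without zone resolution use all TBI cells. The summary
#' reports the count and fraction of parameters with p <= alpha.
#'
#' @param table Validated feature table.
#' @param tail Test tail passed to [compare_two_groups()].
#' @param alpha Significance level (default 0.05).
#' @param zone_scope `"A1"` (default) to restrict zoned reactive cells to
#'   the core, or `"all"` to pool zones.
#' @return List with `tests` (per subpopulation x parameter) and `summary`
#'   (per subpopulation: `n_significant`, `n_parameters`, `fraction`).
#' @export
significance_screen <- function(table, tail = "two.sided", alpha = 0.05,
                                zone_scope = c("A1", "all")) {
  zone_scope <- match.arg(zone_scope)
  table <- validate_feature_table(table)
  tests <- list()
  for (sp in unique(table$subpopulation)) {
    sub <- table[table$subpopulation == sp, , drop = FALSE]
    ctrl <- sub[sub$condition == "control", , drop = FALSE]
    tbi <- sub[sub$condition == "TBI", , drop = FALSE]
    if (zone_scope == "A1" && any(tbi$zone %in% c("A1", "A2")))
      tbi <- tbi[tbi$zone == "A1", , drop = FALSE]
    if (nrow(ctrl) < 2L || nrow(tbi) < 2L) next
    for (p in seq_along(PARAMETER_NAMES)) {
      res <- compare_two_groups(ctrl[[FEATURE_COLUMNS[p]]],
                                tbi[[FEATURE_COLUMNS[p]]], tail = tail)
      res$subpopulation <- sp
      res$parameter <- PARAMETER_NAMES[p]
      tests[[length(tests) + 1L]] <- res
    }
  }
  tests <- do.call(rbind, tests)
  summary <- do.call(rbind, lapply(split(tests, tests$subpopulation),
                                   function(d) data.frame(
    subpopulation = d$subpopulation[1L],
    n_significant = sum(d$p_value <= alpha),
    n_parameters = nrow(d),
    fraction = mean(d$p_value <= alpha),
    stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(tests = tests, summary = summary)
}

#' Proportion of significant parameters per subpopulation
#'
#' Summarises a table of per-parameter test results into absolute counts
#' and fractions of parameters with p <= alpha, per subpopulation.
#'
#' @param tests data.frame with columns `subpopulation`, `parameter`,
#'   `p_value` (one row per pair).
#' @param alpha Significance level.
#' @return data.frame with `subpopulation`, `n_significant`,
#'   `n_parameters`, `fraction`.
#' @export
significant_parameter_summary <- function(tests, alpha = 0.05) {
  out <- do.call(rbind, lapply(split(tests, tests$subpopulation),
                               function(d) data.frame(
    subpopulation = d$subpopulation[1L],
    n_significant = sum(d$p_value <= alpha),
    n_parameters = nrow(d),
    fraction = mean(d$p_value <= alpha),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
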