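#' Bias-corrected sample skewness and excess kurtosis
#'
#' Skewness is the adjusted Fisher-Pearson estimator
#' G1 = g1 * sqrt(n(n-1)) / (n-2); kurtosis is the bias-corrected sample
#' EXCESS kurtosis G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3)), where g1 and
#' g2 are the plug-in moment ratios. With these conventions the normal-
#' sample expectation of the multimodal-index denominator correction term
#' 3(n-1)^2/((n-2)(n-3)) is exact, which identifies the index as a
#' Sarle-type bimodality coefficient.
#'
#' @param values Numeric vector, n >= 4, nonzero variance.
#' @return List with `n`, `m3` (skewness), `m4` (excess kurtosis).
#' @export
sample_moments <- function(values) {
  n <- length(values)
  if (n < 4L) stop("sample moments require n >= 4")
  x <- values - mean(values)
  m2 <- mean(x^2)
  if (m2 == 0) stop("sample moments undefined for zero variance")
  g1 <- mean(x^3) / m2^1.5
  g2 <- mean(x^4) / m2^2 - 3
  m3 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  m4 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  list(n = n, m3 = m3, m4 = m4)
}

#' Multimodal index (Sarle-type bimodality coefficient)
#'
#' MMI = (m3^2 + 1) / (m4 + 3(n-1)^2 / ((n-2)(n-3))) with m3 the
#' bias-corrected sample skewness and m4 the bias-corrected sample excess
#' kurtosis. Large-sample benchmarks: 1/3 for a normal distribution, 5/9
#' (~0.556) for a uniform, and values approaching 1 for well-separated
#' symmetric two-point mixtures; values above the 0.55 threshold flag a
#' parameter as multimodal.
#'
#' @param values Numeric vector (n >= 4, nonzero variance).
#' @param threshold Strict selection threshold (default 0.55).
#' @return One-row data.frame: `n`, `m3`, `m4`, `mmi`, `selected`,
#'   `degenerate` (TRUE when the denominator is not positive; `mmi` is then
#'   `NA` and the parameter is not selected).
#' @export
multimodal_index <- function(values, threshold = 0.55) {
  mom <- sample_moments(values)
  corr <- 3 * (mom$n - 1)^2 / ((mom$n - 2) * (mom$n - 3))
  denom <- mom$m4 + corr
  degenerate <- denom <= 0
  mmi <- if (degenerate) NA_real_ else (mom$m3^2 + 1) / denom
  data.frame(n = mom$n, m3 = mom$m3, m4 = mom$m4, mmi = mmi,
             selected = !degenerate && mmi > threshold,
             degenerate = degenerate)
}

#' Select clustering parameters by multimodal index
#'
#' Computes the MMI of each of the ten morphometric parameters over the
#' clustering population (TBI cells by default) and selects those with MMI
#' strictly greater than the threshold. The full MMI table is returned
#' regardless of selection. An empty selection falls back, with a warning,
#' to all parameters, since downstream clustering needs at least two
#' features.
#'
#' @param table Validated feature table (needs >= 4 cells in the chosen
#'   population).
#' @param threshold Strict MMI threshold (default 0.55).
#' @param population `"TBI"` (default), `"control"`, or `"all"`.
#' @return List with `selected` (character vector of parameter names) and
#'   `mmi_table` (one row per parameter).
#' @export
select_parameters <- function(table, threshold = 0.55, population = "TBI") {
  table <- validate_feature_table(table)
  pop <- switch(population,
                all = table,
                table[table$condition == population, , drop = FALSE])
  if (nrow(pop) < 4L)
    stop("need >= 4 cells in population '", population, "' for MMI")
  mmi_table <- do.call(rbind, lapply(seq_along(PARAMETER_NAMES), function(p) {
    res <- multimodal_index(pop[[FEATURE_COLUMNS[p]]], threshold = threshold)
    cbind(data.frame(parameter = PARAMETER_NAMES[p]), res)
  }))
  selected <- mmi_table$parameter[mmi_table$selected]
  if (length(selected) == 0L) {
    warning("no parameter exceeded MMI threshold ", threshold,
            "; falling back to all parameters")
    selected <- PARAMETER_NAMES
  }
  list(selected = selected, mmi_table = mmi_table)
}
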