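#' Feature-table schema
#'
#' Column names, factor levels and the ten morphometric parameter columns of
#' the per-cell feature table.
#' @name feature_table_schema
NULL

#' @rdname feature_table_schema
#' @export
SUBPOPULATIONS <- c("pial", "protoplasmic_upper", "protoplasmic_lower",
                    "juxtavascular", "fibrous")

#' @rdname feature_table_schema
#' @export
CONDITIONS <- c("control", "TBI")

#' @rdname feature_table_schema
#' @export
ZONES <- c("A1", "A2", "none")

#' @rdname feature_table_schema
#' @export
FEATURE_COLUMNS <- c("area_um2", "convex_hull_area_um2", "perimeter_um",
                     "circularity", "solidity", "length_um", "branches12",
                     "thickness_um3", "intersections", "radius_um")

#' @rdname feature_table_schema
#' @export
PARAMETER_NAMES <- c("area", "convex_hull_area", "perimeter", "circularity",
                     "solidity", "length", "branches12", "thickness",
                     "intersections", "radius")

META_COLUMNS <- c("cell_id", "mouse_id", "subpopulation", "condition",
                  "zone", "x_um", "y_um")

#' Map short parameter names to feature-table column names
#' @param parameters Character vector of parameter names
#'   (see `PARAMETER_NAMES`).
#' @return Matching column names.
#' @export
parameter_column <- function(parameters) {
  idx <- match(parameters, PARAMETER_NAMES)
  if (anyNA(idx))
    stop("unknown parameter(s): ",
         paste(parameters[is.na(idx)], collapse = ", "))
  FEATURE_COLUMNS[idx]
}

#' Validate a feature table
#'
#' Checks column presence, unique cell ids, valid category labels, and that
#' every feature value is finite (no silent imputation: invalid rows are an
#' error). Ratio parameters must lie in (0, 1] up to a small discretization
#' tolerance; counts must be non-negative.
#'
#' @param table A data.frame in the feature-table schema.
#' @param ratio_tol Tolerance above 1 allowed for circularity/solidity
#'   (rasterization slack, default 0.05).
#' @return The validated data.frame.
#' @export
validate_feature_table <- function(table, ratio_tol = 0.05) {
  need <- c(META_COLUMNS, FEATURE_COLUMNS)
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$cell_id))
    stop("duplicate cell_id in feature table")
  check_levels <- function(col, levels) {
    bad <- which(!(table[[col]] %in% levels))
    if (length(bad) > 0L)
      stop("invalid ", col, " label(s) in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), ": ",
           paste(unique(table[[col]][bad]), collapse = ", "))
  }
  check_levels("subpopulation", SUBPOPULATIONS)
  check_levels("condition", CONDITIONS)
  check_levels("zone", ZONES)
  for (col in FEATURE_COLUMNS) {
    v <- table[[col]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("feature '", col, "' has missing or non-finite values in row(s) ",
           paste(utils::head(which(!is.finite(v)), 5L), collapse = ", "))
  }
  for (col in c("circularity", "solidity")) {
    v <- table[[col]]
    if (any(v <= 0) || any(v > 1 + ratio_tol))
      stop("'", col, "' outside (0, 1 + ", ratio_tol, "]")
  }
  for (col in c("branches12", "intersections")) {
    v <- table[[col]]
    if (any(v < 0) || any(v != round(v)))
      stop("'", col, "' must be non-negative integer counts")
  }
  table
}

#' Read a feature-table CSV
#'
#' Comma-separated, UTF-8, '.' decimal, mandatory header with the documented
#' columns. The table is validated; reading and writing round-trip exactly.
#'
#' @param path File path (or connection) to read.
#' @return A validated feature-table data.frame.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, encoding = "UTF-8")
  validate_feature_table(tab)
}

#' Write a feature-table CSV
#' @param table Validated feature table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
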