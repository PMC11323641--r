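#' Clonal analysis of multicolor fluorophore barcodes
#'
#' Sibling cells (clones) share an identical fluorophore barcode: the
#' presence/absence of each of six fluorophores (mT-Sapphire, mCerulean,
#' EGFP, YFP, mKO, mCherry) in each of the two compartments (cytoplasm and
#' nucleus), a 12-entry binary code.
#' @name clonal
NULL

#' @rdname clonal
#' @export
FLUOROPHORES <- c("mTSapphire", "mCerulean", "EGFP", "YFP", "mKO", "mCherry")

#' @rdname clonal
#' @export
CODE_COLUMNS <- as.vector(outer(c("cyt", "nuc"), FLUOROPHORES, paste, sep = "_"))

#' Group cells into clones by exact barcode identity
#'
#' Partitions labelled cells by exact equality of their 12-bit code.
#' Unlabelled cells (all-zero code) are excluded with a warning. Clone ids
#' are ordered by descending clone size.
#'
#' @param cells data.frame with `cell_id`, the 12 `CODE_COLUMNS` (0/1),
#'   and optionally `x_um`, `y_um`, `subpopulation`.
#' @return The input rows of labelled cells with a `clone_id` column added
#'   ("clone01" is the largest clone).
#' @export
group_clones <- function(cells) {
  miss <- setdiff(c("cell_id", CODE_COLUMNS), names(cells))
  if (length(miss) > 0L)
    stop("clone table missing column(s): ", paste(miss, collapse = ", "))
  code_mat <- as.matrix(cells[, CODE_COLUMNS])
  if (!all(code_mat %in% c(0, 1)))
    stop("barcode columns must be binary 0/1")
  unlabeled <- rowSums(code_mat) == 0
  if (any(unlabeled)) {
    warning(sum(unlabeled), " unlabelled cell(s) (all-zero code) excluded")
    cells <- cells[!unlabeled, , drop = FALSE]
    code_mat <- code_mat[!unlabeled, , drop = FALSE]
  }
  code <- apply(code_mat, 1L, paste, collapse = "")
  sizes <- table(code)
  ord <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  ids <- stats::setNames(sprintf("clone%02d", seq_along(ord)), ord)
  cells$clone_code <- code
  cells$clone_id <- unname(ids[code])
  cells
}

#' Clone size, frequency and spatial dispersion statistics
#'
#' Per clone: size, barcode, dispersion (mean Euclidean distance of the
#' members to the clone centroid; 0 for singletons) and the maximum
#' pairwise member distance as an alternative metric. Per subpopulation
#' (a clone is attributed to the majority subpopulation of its members):
#' clone count, percentage of clones, mean clone size, mean dispersion.
#'
#' @param clones Output of [group_clones()] with `x_um`, `y_um`,
#'   `subpopulation` columns.
#' @return List with `per_clone` and `per_subpopulation` data.frames.
#' @export
clone_statistics <- function(clones) {
  need <- c("clone_id", "x_um", "y_um", "subpopulation")
  miss <- setdiff(need, names(clones))
  if (length(miss) > 0L)
    stop("clone statistics need column(s): ", paste(miss, collapse = ", "))
  per_clone <- do.call(rbind, lapply(split(clones, clones$clone_id),
                                     function(d) {
    cx <- mean(d$x_um); cy <- mean(d$y_um)
    disp <- mean(sqrt((d$x_um - cx)^2 + (d$y_um - cy)^2))
    maxd <- if (nrow(d) > 1L) max(stats::dist(cbind(d$x_um, d$y_um))) else 0
    sub <- names(which.max(table(d$subpopulation)))
    data.frame(clone_id = d$clone_id[1L], size = nrow(d),
               code = d$clone_code[1L] %||% NA_character_,
               subpopulation = sub,
               dispersion_um = disp, max_pairwise_um = maxd,
               stringsAsFactors = FALSE)
  }))
  rownames(per_clone) <- NULL
  per_sub <- do.call(rbind, lapply(split(per_clone, per_clone$subpopulation),
                                   function(d) data.frame(
    subpopulation = d$subpopulation[1L],
    n_clones = nrow(d),
    pct_clones = 100 * nrow(d) / nrow(per_clone),
    mean_size = mean(d$size),
    mean_dispersion_um = mean(d$dispersion_um),
    stringsAsFactors = FALSE)))
  rownames(per_sub) <- NULL
  list(per_clone = per_clone, per_subpopulation = per_sub)
}
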