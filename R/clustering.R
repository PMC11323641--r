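#' Z-score normalization of selected parameters
#'
#' Column-wise (x - mean) / sd with the sample standard deviation.
#' Zero-variance columns are dropped with a warning, never divided by
#' zero. Row names carry the cell ids.
#'
#' @param table Validated feature table.
#' @param parameters Parameter names to normalize (default: all ten).
#' @return Numeric matrix (cells x parameters) of z-scores, with attribute
#'   `scaling` (data.frame of the per-parameter mean and sd used).
#' @export
zscore_normalize <- function(table, parameters = PARAMETER_NAMES) {
  table <- validate_feature_table(table)
  if (nrow(table) < 2L) stop("z-score normalization needs >= 2 cells")
  cols <- parameter_column(parameters)
  m <- as.matrix(table[, cols, drop = FALSE])
  colnames(m) <- parameters
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning("dropping zero-variance parameter(s): ",
            paste(parameters[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
    mu <- mu[!zero]; sdv <- sdv[!zero]
  }
  z <- sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  rownames(z) <- table$cell_id
  attr(z, "scaling") <- data.frame(parameter = colnames(z), mean = mu, sd = sdv,
                                   row.names = NULL)
  z
}

# Relabel an integer partition as A, B, C, ... by descending cluster size
# (ties broken by first appearance); 0 stays "noise".
label_by_size <- function(membership) {
  ids <- membership[membership != 0L]
  if (length(ids) == 0L)
    return(rep("noise", length(membership)))
  tab <- table(ids)
  ord <- names(tab)[order(-as.integer(tab), match(names(tab), unique(as.character(ids))))]
  lab <- stats::setNames(LETTERS[seq_along(ord)], ord)
  out <- rep("noise", length(membership))
  nz <- membership != 0L
  out[nz] <- lab[as.character(membership[nz])]
  out
}

#' Agglomerative hierarchical clustering with a distance threshold
#'
#' Euclidean distances on the z-scored matrix, agglomerated with the
#' configured linkage (complete by default, so the cut height keeps
#' Euclidean units in z-space), cut either at `distance_threshold` or, in
#' the alternative mode, into exactly `k` clusters. Cluster labels are
#' assigned A, B, C, ... by descending size.
#'
#' @param z Numeric matrix of z-scores (cells x parameters), >= 2 rows.
#' @param distance_threshold Cut height (default 2.3).
#' @param linkage hclust method (default "complete").
#' @param k Optional fixed cluster count; overrides the threshold cut.
#' @return List with `labels` (named character vector, cell_id -> label),
#'   `k`, `hclust` (the dendrogram object), `method` metadata.
#' @export
hierarchical_cluster <- function(z, distance_threshold = 2.3,
                                 linkage = "complete", k = NULL) {
  if (nrow(z) < 2L) stop("clustering needs >= 2 cells")
  if (is.null(k) && (!is.numeric(distance_threshold) || distance_threshold <= 0))
    stop("distance_threshold must be > 0")
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = linkage)
  membership <- if (!is.null(k) && is.finite(k))
    stats::cutree(hc, k = as.integer(k))
  else
    stats::cutree(hc, h = distance_threshold)
  labels <- label_by_size(membership)
  names(labels) <- rownames(z)
  list(labels = labels, k = length(unique(labels)), hclust = hc,
       method = list(linkage = linkage,
                     distance_threshold = if (is.null(k)) distance_threshold else NA,
                     k = k))
}

#' Principal component analysis of z-scored features
#'
#' Eigendecomposition of the covariance of the z-scores (equivalently,
#' correlation-matrix PCA of the raw features). Returns scores, loadings
#' (orthonormal columns) and the explained-variance fraction per component.
#'
#' @param z Z-score matrix (cells x parameters).
#' @param n_components Number of components to keep (default: full rank;
#'   larger requests are truncated with a warning).
#' @return List with `scores`, `loadings`, `explained` (fractions) and
#'   `sdev`.
#' @export
pca_features <- function(z, n_components = NULL) {
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warning("n_components ", n_components, " exceeds rank ", rank,
            "; truncating")
    n_components <- rank
  }
  keep <- seq_len(n_components)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       explained = explained[keep],
       sdev = pc$sdev[keep])
}

#' t-SNE embedding of z-scored features
#'
#' Two-dimensional Barnes-Hut-free (exact) t-SNE, deterministic for a given
#' seed. Requires n > 3 * perplexity.
#'
#' @param z Z-score matrix (cells x parameters).
#' @param perplexity t-SNE perplexity (default 5).
#' @param seed Random seed (default 0).
#' @param max_iter Optimisation iterations (default 1000).
#' @return List with `embedding` (n x 2 matrix, rownames = cell ids),
#'   `kl_divergence`, `perplexity`, `seed`.
#' @export
tsne_embed <- function(z, perplexity = 5, seed = 0, max_iter = 1000) {
  n <- nrow(z)
  if (n - 1 < 3 * perplexity)
    stop("t-SNE requires n > 3 * perplexity + 1 (n = ", n,
         ", perplexity = ", perplexity, ")")
  # duplicate rows are collapsed before embedding and mapped back to the
  # same coordinates, so they remain exactly coincident
  key <- apply(z, 1L, paste, collapse = "\r")
  uniq <- !duplicated(key)
  zu <- z[uniq, , drop = FALSE]
  if (nrow(zu) - 1 < 3 * perplexity)
    stop("t-SNE requires more than 3 * perplexity + 1 distinct rows")
  set.seed(seed)
  fit <- Rtsne::Rtsne(zu, dims = 2, perplexity = perplexity,
                      theta = 0, pca = FALSE, max_iter = max_iter,
                      check_duplicates = FALSE, verbose = FALSE)
  emb <- fit$Y[match(key, key[uniq]), , drop = FALSE]
  rownames(emb) <- rownames(z)
  colnames(emb) <- c("tsne_x", "tsne_y")
  list(embedding = emb,
       kl_divergence = utils::tail(fit$itercosts, 1L),
       perplexity = perplexity, seed = seed)
}
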