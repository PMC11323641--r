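#' Per-cluster confidence intervals
#'
#' t-based confidence intervals, mean +/- t(1 - alpha/2, n - 1) * sd /
#' sqrt(n), for each (cluster, parameter). Singleton clusters have no CI
#' and are excluded with a warning.
#'
#' @param z Z-score matrix (cells x parameters) or any numeric matrix with
#'   named columns.
#' @param labels Cluster label per row of `z`.
#' @param level Confidence level (default 0.95).
#' @return data.frame with `cluster`, `parameter`, `n`, `mean`, `ci_low`,
#'   `ci_high`.
#' @export
cluster_ci <- function(z, labels, level = 0.95) {
  stopifnot(nrow(z) == length(labels))
  alpha <- 1 - level
  out <- list()
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    if (length(rows) < 2L) {
      warning("cluster '", cl, "' is a singleton; CI undefined, excluded")
      next
    }
    for (p in colnames(z)) {
      v <- z[rows, p]
      m <- mean(v)
      half <- stats::qt(1 - alpha / 2, length(v) - 1L) *
        stats::sd(v) / sqrt(length(v))
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, parameter = p, n = length(v), mean = m,
        ci_low = m - half, ci_high = m + half, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Parameters defining the first-level nodes; the per-cell response score is
# the mean z-score over those that are available.
FIRST_LEVEL_PARAMETERS <- c("perimeter", "intersections", "radius")

response_score <- function(z) {
  cols <- intersect(FIRST_LEVEL_PARAMETERS, colnames(z))
  if (length(cols) == 0L)
    stop("none of the first-level parameters (",
         paste(FIRST_LEVEL_PARAMETERS, collapse = ", "),
         ") are present")
  rowMeans(z[, cols, drop = FALSE])
}

# Group clusters on one value vector: order clusters by mean, compute each
# cluster's t-CI, chain-merge adjacent clusters whose CIs overlap. Returns
# groups (lists of cluster labels), their pooled intervals, and the
# cut-offs (midpoints of the CI gaps between adjacent groups).
group_by_ci <- function(values, labels, clusters, level = 0.95) {
  ci <- do.call(rbind, lapply(clusters, function(cl) {
    v <- values[labels == cl]
    m <- mean(v)
    half <- if (length(v) >= 2L)
      stats::qt(1 - (1 - level) / 2, length(v) - 1L) * stats::sd(v) / sqrt(length(v))
    else 0
    data.frame(cluster = cl, mean = m, lo = m - half, hi = m + half,
               stringsAsFactors = FALSE)
  }))
  ci <- ci[order(ci$mean), , drop = FALSE]
  groups <- list(list(clusters = ci$cluster[1L], lo = ci$lo[1L], hi = ci$hi[1L]))
  for (i in seq_len(nrow(ci))[-1L]) {
    g <- groups[[length(groups)]]
    if (ci$lo[i] <= g$hi) {   # CI overlap: merge into the current group
      g$clusters <- c(g$clusters, ci$cluster[i])
      g$lo <- min(g$lo, ci$lo[i])
      g$hi <- max(g$hi, ci$hi[i])
      groups[[length(groups)]] <- g
    } else {
      groups[[length(groups) + 1L]] <- list(clusters = ci$cluster[i],
                                            lo = ci$lo[i], hi = ci$hi[i])
    }
  }
  cutoffs <- if (length(groups) > 1L)
    vapply(seq_len(length(groups) - 1L), function(i)
      (groups[[i]]$hi + groups[[i + 1L]]$lo) / 2, 0)
  else numeric(0)
  list(groups = groups, cutoffs = cutoffs)
}

RESPONSE_CATEGORIES <- c("moderate", "strong", "very_strong")

SUBLABEL_VOCAB <- list(convex_hull_area = c("medium", "large"),
                       length = c("short", "medium", "long"),
                       thickness = c("medium", "large"))

sublabel_names <- function(parameter, k) {
  vocab <- SUBLABEL_VOCAB[[parameter]]
  if (is.null(vocab)) vocab <- c("low", "medium", "high")
  if (k > length(vocab))
    return(c(vocab, paste0("tier", seq.int(length(vocab) + 1L, k))))
  vocab[round(seq(1, length(vocab), length.out = k))]
}

#' Build the logical tree of reactive-response categories
#'
#' First-level nodes are defined by the per-cluster mean response score
#' (mean z of perimeter, intersections and radius): clusters are ordered by
#' that score and merged when their 95% CIs overlap; cut-offs sit at the
#' midpoints of the CI gaps between the resulting groups. Each first-level
#' group carries a response category -- from `category_map` when given
#' (the default when exactly 8 clusters A-H are present maps C+D to
#' moderate, A+B to strong and E-H to very strong), otherwise by ascending
#' score tercile. Within each group, deeper nodes split the remaining
#' clusters on convex hull area, then length, then thickness, by the same
#' CI rule, and attach ordered sub-labels (medium/large on convex hull and
#' thickness, short/medium/long on length).
#'
#' @param z Z-score matrix with parameter column names (cells in rows).
#' @param labels Cluster label per cell.
#' @param category_map Optional named character vector, cluster ->
#'   category.
#' @param level Confidence level for the CIs (default 0.95).
#' @param sublevel_parameters Ordered parameters for the deeper nodes.
#' @return An object of class `response_tree`: a recursive node list plus
#'   `scaling`-free metadata used by [classify_cell()].
#' @export
build_response_tree <- function(z, labels, category_map = NULL, level = 0.95,
                                sublevel_parameters = c("convex_hull_area",
                                                        "length", "thickness")) {
  keep <- labels != "noise"
  z <- z[keep, , drop = FALSE]
  labels <- labels[keep]
  sizes <- table(labels)
  usable <- names(sizes)[sizes >= 2L]
  if (length(usable) < 1L) stop("no cluster with n >= 2")
  drop <- setdiff(names(sizes), usable)
  if (length(drop) > 0L)
    warning("singleton cluster(s) excluded from tree building: ",
            paste(drop, collapse = ", "))
  in_use <- labels %in% usable
  z <- z[in_use, , drop = FALSE]
  labels <- labels[in_use]
  score <- response_score(z)
  lvl1 <- group_by_ci(score, labels, sort(unique(labels)), level)
  n_groups <- length(lvl1$groups)
  if (is.null(category_map) && length(usable) == 8L &&
      setequal(usable, LETTERS[1:8])) {
    category_map <- c(A = "strong", B = "strong", C = "moderate",
                      D = "moderate", E = "very_strong", F = "very_strong",
                      G = "very_strong", H = "very_strong")
  }
  group_category <- function(g, i) {
    if (!is.null(category_map)) {
      cats <- category_map[g$clusters]
      names(which.max(table(factor(cats, levels = RESPONSE_CATEGORIES))))
    } else {
      RESPONSE_CATEGORIES[ceiling(3 * i / n_groups)]
    }
  }
  children <- lapply(seq_len(n_groups), function(i) {
    g <- lvl1$groups[[i]]
    build_subtree(z, labels, g$clusters, group_category(g, i),
                  sublevel_parameters, level, sublabels = character(0))
  })
  structure(list(parameter = "response_score",
                 definition = FIRST_LEVEL_PARAMETERS,
                 cutoffs = lvl1$cutoffs,
                 children = children,
                 level = level),
            class = "response_tree")
}

build_subtree <- function(z, labels, clusters, category, params, level,
                          sublabels) {
  if (length(clusters) >= 2L && length(params) >= 1L) {
    for (pi in seq_along(params)) {
      p <- params[pi]
      if (!p %in% colnames(z)) next
      grp <- group_by_ci(z[, p], labels, clusters, level)
      if (length(grp$groups) > 1L) {
        names <- sublabel_names(p, length(grp$groups))
        children <- lapply(seq_along(grp$groups), function(i) {
          build_subtree(z, labels, grp$groups[[i]]$clusters, category,
                        params[-seq_len(pi)], level,
                        c(sublabels, stats::setNames(names[i], p)))
        })
        return(list(parameter = p, cutoffs = grp$cutoffs,
                    children = children))
      }
    }
  }
  list(category = category, clusters = clusters, sublabels = sublabels)
}

#' Classify a cell through the response tree
#'
#' Routes a cell's z-scored features through the tree's cut-offs; a value
#' exactly equal to a cut-off routes to the upper branch. Returns the leaf
#' category, the accumulated sub-labels and the routing path.
#'
#' @param tree A `response_tree`.
#' @param z_row Named numeric vector of the cell's z-scored parameters.
#' @return List with `category`, `sublabels`, `path` (character vector of
#'   "parameter=interval index" steps), `clusters` (the leaf's clusters).
#' @export
classify_cell <- function(tree, z_row) {
  get_value <- function(node) {
    if (identical(node$parameter, "response_score")) {
      need <- intersect(tree$definition, names(z_row))
      if (length(need) == 0L)
        stop("missing parameter(s): ", paste(tree$definition, collapse = ", "))
      mean(z_row[need])
    } else {
      if (!node$parameter %in% names(z_row))
        stop("missing parameter: ", node$parameter)
      unname(z_row[[node$parameter]])
    }
  }
  node <- unclass(tree)
  path <- character(0)
  while (is.null(node$category)) {
    v <- get_value(node)
    idx <- findInterval(v, node$cutoffs) + 1L  # value == cutoff -> upper
    path <- c(path, paste0(node$parameter, ":", idx))
    node <- node$children[[idx]]
  }
  list(category = node$category, sublabels = node$sublabels, path = path,
       clusters = node$clusters)
}

#' Classify every row of a z-score matrix
#' @param tree A `response_tree`.
#' @param z Z-score matrix (cells x parameters).
#' @return data.frame with `cell_id`, `category`, `sublabels` (collapsed).
#' @export
classify_cells <- function(tree, z) {
  out <- lapply(seq_len(nrow(z)), function(i) {
    res <- classify_cell(tree, z[i, ])
    data.frame(cell_id = rownames(z)[i] %||% as.character(i),
               category = res$category,
               sublabels = paste(paste0(names(res$sublabels), "=",
                                        res$sublabels), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Category of each cluster implied by a response tree
#' @param tree A `response_tree`.
#' @return Named character vector, cluster -> category.
#' @export
tree_category_map <- function(tree) {
  out <- character(0)
  walk <- function(node) {
    if (!is.null(node$category)) {
      out[node$clusters] <<- node$category
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(unclass(tree))
  out
}

#' Serialize a response tree to JSON
#' @param tree A `response_tree`.
#' @param path Optional file to write.
#' @return JSON string (invisibly when written to file).
#' @export
response_tree_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Composition frequencies of subpopulations within response categories
#'
#' Absolute counts and relative percentages of each subpopulation within
#' each category, and of each category within each subpopulation; each
#' margin's relative values sum to 100.
#'
#' @param categories Character vector of response categories per cell.
#' @param subpopulations Character vector of subpopulations per cell.
#' @return List of data.frames: `counts`, `pct_within_category`,
#'   `pct_within_subpopulation`.
#' @export
composition_frequencies <- function(categories, subpopulations) {
  tab <- table(category = categories, subpopulation = subpopulations)
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts)[3L] <- "n"
  pct_cat <- as.data.frame(prop.table(tab, margin = 1L) * 100,
                           stringsAsFactors = FALSE)
  names(pct_cat)[3L] <- "pct"
  pct_sub <- as.data.frame(prop.table(tab, margin = 2L) * 100,
                           stringsAsFactors = FALSE)
  names(pct_sub)[3L] <- "pct"
  list(counts = counts, pct_within_category = pct_cat,
       pct_within_subpopulation = pct_sub)
}
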