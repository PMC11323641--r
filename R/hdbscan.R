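#' Density-based hierarchical clustering (HDBSCAN)
#'
#' Full HDBSCAN: core distances at `min_samples` neighbours (counting the
#' point itself), mutual-reachability distances, single-linkage hierarchy,
#' condensation of the tree at `min_cluster_size`, cluster stability
#' (excess of mass) selection, and noise labelling for points in no
#' selected cluster. A single undivided cluster is not selected, so a
#' dataset with no density split comes back all noise (a valid outcome).
#'
#' @param embedding Numeric matrix (points x dims), typically the 2D t-SNE
#'   embedding.
#' @param min_cluster_size Minimum cluster size (default 10).
#' @param min_samples Neighbour count for core distances (default:
#'   `min_cluster_size`).
#' @return List with `labels` (character, A, B, ... by descending size,
#'   "noise" for unclustered points; named by rownames), `n_clusters`, and
#'   `method` metadata.
#' @export
hdbscan_cluster <- function(embedding, min_cluster_size = 10,
                            min_samples = min_cluster_size) {
  x <- as.matrix(embedding)
  n <- nrow(x)
  meta <- list(min_cluster_size = min_cluster_size, min_samples = min_samples)
  if (n < min_cluster_size) {
    labels <- rep("noise", n)
    names(labels) <- rownames(x)
    return(list(labels = labels, n_clusters = 0L, method = meta))
  }
  d <- as.matrix(stats::dist(x))
  core <- apply(d, 1L, function(row) sort(row)[min_samples])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  cond <- condense_tree(hc, n, min_cluster_size)
  selected <- select_clusters_eom(cond)
  membership <- assign_condensed_labels(cond, selected, n)
  labels <- label_by_size(membership)
  names(labels) <- rownames(x)
  list(labels = labels, n_clusters = length(setdiff(unique(labels), "noise")),
       method = meta)
}

# Cap for lambda = 1 / height when duplicate points give zero merge heights.
LAMBDA_CAP <- 1e12

# Condense a single-linkage hierarchy. Walking from the root down, a merge
# node whose two sides both reach min_cluster_size is a true split: the
# current cluster's remaining members (exactly the leaves under that node)
# leave it there, and two child clusters are born. Otherwise the small
# side's points fall out of the current cluster as noise at the split's
# lambda (= 1 / merge height) and the walk continues down the big side
# within the same cluster. Stability(c) = sum over members of
# (lambda_leave - lambda_birth).
condense_tree <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  n_merge <- nrow(merge)
  leaves <- vector("list", n_merge)   # leaf point indices under each merge
  for (i in seq_len(n_merge)) {
    grab <- function(v) if (v < 0) -v else leaves[[v]]
    leaves[[i]] <- c(grab(merge[i, 1L]), grab(merge[i, 2L]))
  }
  lambda_of <- function(h) if (h <= 0) LAMBDA_CAP else min(1 / h, LAMBDA_CAP)

  cluster_parent <- integer(1); cluster_parent[1L] <- 0L
  cluster_birth <- numeric(1); cluster_birth[1L] <- 0
  cluster_stability <- numeric(1)
  point_cluster <- integer(n)   # condensed-tree attachment of each point
  point_lambda <- numeric(n)

  stack <- list(c(n_merge, 1L))  # (merge node, cluster id)
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1L]; cl <- top[2L]
    lam <- lambda_of(height[node])
    ch <- merge[node, ]
    size_of <- function(v) if (v < 0) 1L else length(leaves[[v]])
    sizes <- c(size_of(ch[1L]), size_of(ch[2L]))
    if (all(sizes >= mcs)) {
      # true split: remaining mass leaves cl here, two children are born
      cluster_stability[cl] <- cluster_stability[cl] +
        length(leaves[[node]]) * (lam - cluster_birth[cl])
      for (side in 1:2) {
        cluster_parent <- c(cluster_parent, cl)
        cluster_birth <- c(cluster_birth, lam)
        cluster_stability <- c(cluster_stability, 0)
        stack[[length(stack) + 1L]] <- c(ch[side], length(cluster_parent))
      }
    } else {
      for (side in 1:2) {
        if (sizes[side] < mcs) {
          pts <- if (ch[side] < 0) -ch[side] else leaves[[ch[side]]]
          point_cluster[pts] <- cl
          point_lambda[pts] <- lam
          cluster_stability[cl] <- cluster_stability[cl] +
            length(pts) * (lam - cluster_birth[cl])
        } else {
          stack[[length(stack) + 1L]] <- c(ch[side], cl)
        }
      }
    }
  }
  list(parent = cluster_parent, birth = cluster_birth,
       stability = cluster_stability,
       point_cluster = point_cluster, point_lambda = point_lambda)
}

# Excess-of-mass cluster selection; the root cluster is never selected.
select_clusters_eom <- function(cond) {
  k <- length(cond$parent)
  if (k <= 1L) return(integer(0))
  children <- split(seq_len(k), factor(cond$parent, levels = seq_len(k)))
  selected <- logical(k)
  subtree_stab <- numeric(k)
  for (cl in rev(seq_len(k))) {     # children have larger ids than parents
    ch <- children[[cl]]
    child_sum <- if (length(ch) > 0L) sum(subtree_stab[ch]) else 0
    if (cl == 1L) {                 # root: never selected
      subtree_stab[cl] <- child_sum
    } else if (length(ch) == 0L || cond$stability[cl] >= child_sum) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- cond$stability[cl]
      desc <- ch                    # deselect all descendants
      while (length(desc) > 0L) {
        selected[desc] <- FALSE
        desc <- unlist(children[desc], use.names = FALSE)
      }
    } else {
      subtree_stab[cl] <- child_sum
    }
  }
  which(selected)
}

# Map each point to its nearest selected ancestor in the condensed tree
# (0 = noise). A point attached above every selected cluster is noise.
assign_condensed_labels <- function(cond, selected, n) {
  membership <- integer(n)
  if (length(selected) == 0L) return(membership)
  sel <- logical(length(cond$parent))
  sel[selected] <- TRUE
  for (p in seq_len(n)) {
    cl <- cond$point_cluster[p]
    while (cl > 0L) {
      if (sel[cl]) { membership[p] <- cl; break }
      cl <- cond$parent[cl]
    }
  }
  membership
}
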