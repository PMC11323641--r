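#' Count primary and secondary branches
#'
#' A primary branch is a maximal unbranched path starting at a (non-soma)
#' child of a soma node (or of the root when no node is typed as soma). When
#' a primary branch ends at a branch point, each child of that endpoint
#' starts a secondary branch. The feature `branches12` is the number of
#' primary plus secondary branches.
#'
#' @param skel A `skeleton`.
#' @return Integer count of primary + secondary branches.
#' @export
branch_counts <- function(skel) {
  skel <- validate_skeleton(skel)
  nodes <- skel$nodes
  children <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  kids <- function(id) children[[as.character(id)]]
  is_soma <- stats::setNames(nodes$type_code == 1L, nodes$node_id)
  attach_ids <- nodes$node_id[nodes$type_code == 1L]
  if (length(attach_ids) == 0L)
    attach_ids <- nodes$node_id[nodes$parent_id == -1L]
  starts <- unlist(lapply(attach_ids, kids), use.names = FALSE)
  starts <- starts[!is_soma[as.character(starts)]]
  if (length(starts) == 0L) return(0L)
  # walk a maximal unbranched path from `id`; return its endpoint
  walk <- function(id) {
    repeat {
      k <- kids(id)
      if (length(k) != 1L) return(id)
      id <- k
    }
  }
  n_primary <- length(starts)
  n_secondary <- 0L
  for (s in starts) {
    endpoint <- walk(s)
    k <- kids(endpoint)
    if (length(k) >= 2L) n_secondary <- n_secondary + length(k)
  }
  n_primary + n_secondary
}

#' Total process length of a skeleton
#'
#' Sum of Euclidean lengths of all parent-child segments, excluding
#' intra-soma (type-1 to type-1) segments.
#'
#' @param skel A `skeleton`.
#' @return Length in micrometres.
#' @export
total_length <- function(skel) {
  skel <- validate_skeleton(skel)
  seg <- skeleton_segments(skel)
  seg <- seg[!seg$intra_soma, , drop = FALSE]
  if (nrow(seg) == 0L) return(0)
  sum(sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 + (seg$z2 - seg$z1)^2))
}

#' Cell thickness (volume above threshold)
#'
#' Two modes. Stack mode: the count of voxels with intensity above
#' `threshold` times the stack maximum, multiplied by the voxel volume
#' (the "relative to 0.05 threshold" volume). Skeleton mode (fallback when
#' no intensity stack is available, flagged in the result): the sum of
#' conical-frustum volumes pi*h*(r1^2 + r1*r2 + r2^2)/3 over parent-child
#' segments, using the traced radii.
#'
#' @param x A 3D numeric array (intensity stack) or a `skeleton`.
#' @param voxel_dims Voxel edge lengths in micrometres (length 3), stack
#'   mode only.
#' @param threshold Relative intensity threshold (default 0.05).
#' @return A list with `value` (um^3) and `mode` ("stack" or "skeleton").
#' @export
thickness <- function(x, voxel_dims = c(1, 1, 1), threshold = 0.05) {
  if (inherits(x, "skeleton")) {
    seg <- skeleton_segments(x)
    seg <- seg[!seg$intra_soma, , drop = FALSE]
    if (nrow(seg) == 0L || all(seg$r1 == 0 & seg$r2 == 0))
      stop("skeleton-mode thickness requires traced radii (all radii are 0)")
    h <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 + (seg$z2 - seg$z1)^2)
    v <- pi * h * (seg$r1^2 + seg$r1 * seg$r2 + seg$r2^2) / 3
    return(list(value = sum(v), mode = "skeleton"))
  }
  if (!is.array(x) || !is.numeric(x))
    stop("x must be an intensity array or a skeleton")
  mx <- max(x)
  if (mx <= 0) stop("intensity stack is all zero")
  n_above <- sum(x > threshold * mx)
  list(value = n_above * prod(voxel_dims), mode = "stack")
}

#' Sholl intersection profile
#'
#' Counts, for concentric spherical shells centred on the soma centroid and
#' spaced `step` micrometres apart, the number of parent-child segments that
#' cross (or tangentially touch) each shell. A segment crossing a shell is
#' counted once; an endpoint exactly on a shell counts as a crossing. Shells
#' run from `step` up to the first shell at or beyond the farthest node.
#'
#' @param skel A `skeleton` with at least one non-soma node.
#' @param step Shell spacing in micrometres, > 0 (default 2).
#' @return An object of class `sholl_profile`: a list with `soma_center`,
#'   `step`, `radii`, `counts`.
#' @export
sholl_profile <- function(skel, step = 2) {
  skel <- validate_skeleton(skel)
  if (step <= 0) stop("step must be > 0")
  if (all(skel$nodes$type_code == 1L))
    stop("Sholl profile requires at least one non-soma node")
  ctr <- soma_center(skel)
  seg <- skeleton_segments(skel)
  seg <- seg[!seg$intra_soma, , drop = FALSE]
  d_node <- sqrt((skel$nodes$x - ctr[1L])^2 + (skel$nodes$y - ctr[2L])^2 +
                   (skel$nodes$z - ctr[3L])^2)
  n_shell <- ceiling(max(d_node) / step)
  radii <- step * seq_len(max(n_shell, 1L))
  # per segment: nearest and farthest distance from the centre to the segment
  ax <- seg$x1 - ctr[1L]; ay <- seg$y1 - ctr[2L]; az <- seg$z1 - ctr[3L]
  vx <- seg$x2 - seg$x1; vy <- seg$y2 - seg$y1; vz <- seg$z2 - seg$z1
  vv <- vx^2 + vy^2 + vz^2
  t_star <- ifelse(vv > 0, pmin(pmax(-(ax * vx + ay * vy + az * vz) / vv, 0), 1), 0)
  px <- ax + t_star * vx; py <- ay + t_star * vy; pz <- az + t_star * vz
  d_min <- sqrt(px^2 + py^2 + pz^2)
  d1 <- sqrt(ax^2 + ay^2 + az^2)
  d2 <- sqrt((ax + vx)^2 + (ay + vy)^2 + (az + vz)^2)
  d_max <- pmax(d1, d2)
  counts <- vapply(radii, function(r) sum(d_min <= r & r <= d_max), 0L)
  structure(list(soma_center = ctr, step = step, radii = radii,
                 counts = as.integer(counts)),
            class = "sholl_profile")
}

#' Sholl profile summary
#'
#' The maximum intersection count, the critical radius (smallest shell
#' attaining it) and the enclosing radius (largest shell with a nonzero
#' count). In the feature table, `intersections` maps to the maximum count
#' and `radius` to the enclosing radius.
#'
#' @param profile A `sholl_profile`.
#' @return List with `max_intersections`, `critical_radius`,
#'   `enclosing_radius`.
#' @export
sholl_summary <- function(profile) {
  counts <- profile$counts
  if (all(counts == 0L)) stop("Sholl profile has no nonzero shell")
  mx <- max(counts)
  list(max_intersections = mx,
       critical_radius = profile$radii[which(counts == mx)[1L]],
       enclosing_radius = max(profile$radii[counts > 0L]))
}

#' Three-segment decomposition of a Sholl profile
#'
#' The peak segment is the maximal contiguous run of shells with count >=
#' `peak_fraction` times the maximum that contains the critical radius; the
#' growth segment runs from the first nonzero shell up to the peak start,
#' and the decline segment from after the peak through the enclosing radius.
#'
#' @param profile A `sholl_profile` with at least 3 nonzero shells.
#' @param peak_fraction Fraction of the maximum count defining the peak run
#'   (default 0.9).
#' @return A list of three data.frames (`growth`, `peak`, `decline`), each
#'   with `radius` and `count` columns (growth or decline may be empty).
#' @export
segment_sholl <- function(profile, peak_fraction = 0.9) {
  counts <- profile$counts
  radii <- profile$radii
  nz <- which(counts > 0L)
  if (length(nz) < 3L)
    stop("degenerate Sholl profile: fewer than 3 nonzero shells")
  first_nz <- nz[1L]
  enclosing <- nz[length(nz)]
  mx <- max(counts)
  crit <- which(counts == mx)[1L]
  hi <- counts >= peak_fraction * mx
  peak_lo <- crit
  while (peak_lo > first_nz && hi[peak_lo - 1L]) peak_lo <- peak_lo - 1L
  peak_hi <- crit
  while (peak_hi < enclosing && hi[peak_hi + 1L]) peak_hi <- peak_hi + 1L
  seg_df <- function(idx) data.frame(radius = radii[idx], count = counts[idx])
  list(growth = seg_df(seq_len(peak_lo - first_nz) + first_nz - 1L),
       peak = seg_df(peak_lo:peak_hi),
       decline = if (peak_hi < enclosing) seg_df((peak_hi + 1L):enclosing)
                 else seg_df(integer(0)))
}

#' Extract the ten morphometric parameters for one cell
#'
#' Combines the 2D mask metrics, skeleton metrics, thickness (stack mode
#' when an intensity stack is supplied, otherwise the skeleton frustum
#' fallback) and the Sholl summary into one feature-table row.
#'
#' @param mask A `cell_mask`.
#' @param skel A `skeleton`.
#' @param stack Optional 3D intensity array for stack-mode thickness.
#' @param voxel_dims Voxel dimensions for stack mode (um, length 3).
#' @param metadata Named list with `cell_id`, `mouse_id`, `subpopulation`,
#'   `condition`, `zone`, `x_um`, `y_um` (missing entries get defaults).
#' @param sholl_step Sholl shell spacing (um).
#' @return A one-row data.frame in the feature-table schema, with attribute
#'   `thickness_mode`.
#' @export
extract_features <- function(mask, skel, stack = NULL, voxel_dims = c(1, 1, 1),
                             metadata = list(), sholl_step = 2) {
  cell_id <- metadata$cell_id %||% skel$cell_id
  wrap <- function(expr) tryCatch(expr, error = function(e)
    stop("cell '", cell_id, "': ", conditionMessage(e), call. = FALSE))
  if (is.null(skel)) stop("cell '", cell_id, "': missing skeleton")
  if (is.null(mask)) stop("cell '", cell_id, "': missing mask")
  s2 <- wrap(shape_features_2d(mask))
  th <- wrap(if (is.null(stack)) thickness(skel) else
    thickness(stack, voxel_dims = voxel_dims))
  prof <- wrap(sholl_profile(skel, step = sholl_step))
  sh <- wrap(sholl_summary(prof))
  rec <- data.frame(
    cell_id = cell_id,
    mouse_id = metadata$mouse_id %||% "m1",
    subpopulation = metadata$subpopulation %||% "protoplasmic_upper",
    condition = metadata$condition %||% "control",
    zone = metadata$zone %||% "none",
    x_um = metadata$x_um %||% 0,
    y_um = metadata$y_um %||% 0,
    area_um2 = s2$area,
    convex_hull_area_um2 = s2$convex_hull_area,
    perimeter_um = s2$perimeter,
    circularity = s2$circularity,
    solidity = s2$solidity,
    length_um = wrap(total_length(skel)),
    branches12 = wrap(branch_counts(skel)),
    thickness_um3 = th$value,
    intersections = sh$max_intersections,
    radius_um = sh$enclosing_radius,
    stringsAsFactors = FALSE)
  attr(rec, "thickness_mode") <- th$mode
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
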