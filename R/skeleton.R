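#' Skeleton objects: traced cell geometry
#'
#' A `skeleton` holds a rooted tree of 3D nodes with radii, the substrate for
#' total process length, branch counts, frustum thickness and Sholl analysis.
#' Node semantics follow the SWC convention: `type_code == 1` marks soma
#' nodes, `parent_id == -1` marks the root, coordinates and radii are in
#' micrometres.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param nodes A data.frame with columns `node_id`, `type_code`, `x`, `y`,
#'   `z`, `radius`, `parent_id`.
#' @return An object of class `skeleton`: a list with `cell_id` and `nodes`.
#' @export
skeleton <- function(cell_id, nodes) {
  obj <- structure(list(cell_id = as.character(cell_id),
                        nodes = as.data.frame(nodes)),
                   class = "skeleton")
  validate_skeleton(obj)
}

#' Validate a skeleton against its structural invariants
#'
#' Checks: at least one node, unique node ids, exactly one root, all parent
#' ids resolve, the graph is acyclic and connected, radii are non-negative.
#'
#' @param skel A `skeleton` object.
#' @return The validated skeleton, invisibly unchanged.
#' @export
validate_skeleton <- function(skel) {
  nodes <- skel$nodes
  need <- c("node_id", "type_code", "x", "y", "z", "radius", "parent_id")
  missing_cols <- setdiff(need, names(nodes))
  if (length(missing_cols) > 0L)
    stop("skeleton nodes missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(nodes) == 0L)
    stop("skeleton must contain at least one node")
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in skeleton '", skel$cell_id, "'")
  if (any(nodes$node_id <= 0))
    stop("node_id must be a positive integer")
  if (any(nodes$radius < 0))
    stop("radius must be >= 0")
  roots <- nodes$parent_id == -1L
  if (sum(roots) != 1L)
    stop("skeleton must have exactly one root (parent_id -1), found ", sum(roots))
  non_root <- nodes$parent_id[!roots]
  if (!all(non_root %in% nodes$node_id))
    stop("dangling parent_id in skeleton '", skel$cell_id, "'")
  # connectivity / acyclicity: walk each node to the root
  parent_of <- stats::setNames(nodes$parent_id, nodes$node_id)
  n <- nrow(nodes)
  for (id in nodes$node_id) {
    seen <- 0L
    cur <- id
    while (parent_of[[as.character(cur)]] != -1L) {
      cur <- parent_of[[as.character(cur)]]
      seen <- seen + 1L
      if (seen > n) stop("cycle detected in skeleton '", skel$cell_id, "'")
    }
  }
  skel
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton> cell", x$cell_id, "-", nrow(x$nodes), "nodes\n")
  invisible(x)
}

#' Parse an SWC trace into a skeleton
#'
#' Reads the standard 7-column whitespace-delimited SWC dialect
#' (`node_id type x y z radius parent_id`), with `#` comment lines.
#' Coordinates and radii are taken to be in micrometres.
#'
#' @param text Either a character vector of lines, a single string with
#'   embedded newlines, or a file path to read.
#' @param cell_id Cell identifier to attach; defaults to "cell".
#' @return A validated `skeleton`.
#' @export
parse_swc <- function(text, cell_id = "cell") {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(text)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L)
    stop("SWC input contains no node lines")
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad) > 0L)
    stop("SWC line ", line_no[bad[1L]], " does not have 7 columns")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    stop("SWC line ", line_no[which(rowSums(is.na(m)) > 0)[1L]],
         " contains a non-numeric field")
  nodes <- data.frame(node_id = as.integer(m[, 1L]),
                      type_code = as.integer(m[, 2L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L],
                      radius = m[, 6L],
                      parent_id = as.integer(m[, 7L]))
  dup <- which(duplicated(nodes$node_id))
  if (length(dup) > 0L)
    stop("duplicate node_id ", nodes$node_id[dup[1L]], " at SWC line ",
         line_no[dup[1L]])
  dangling <- which(nodes$parent_id != -1L & !(nodes$parent_id %in% nodes$node_id))
  if (length(dangling) > 0L)
    stop("dangling parent_id ", nodes$parent_id[dangling[1L]], " at SWC line ",
         line_no[dangling[1L]])
  skeleton(cell_id, nodes)
}

#' Serialize a skeleton to SWC text
#'
#' Emits standard 7-column SWC with nodes topologically ordered (every parent
#' line precedes its children).
#'
#' @param skel A valid `skeleton`.
#' @return Character vector of SWC lines.
#' @export
serialize_swc <- function(skel) {
  skel <- validate_skeleton(skel)
  nodes <- skel$nodes
  # topological order: repeated passes emitting nodes whose parent was emitted
  emitted <- logical(nrow(nodes))
  order_idx <- integer(0)
  avail <- nodes$parent_id == -1L
  while (any(avail & !emitted)) {
    nxt <- which(avail & !emitted)
    order_idx <- c(order_idx, nxt)
    emitted[nxt] <- TRUE
    avail <- nodes$parent_id %in% nodes$node_id[emitted]
    avail[nodes$parent_id == -1L] <- TRUE
  }
  nodes <- nodes[order_idx, , drop = FALSE]
  sprintf("%d %d %.12g %.12g %.12g %.12g %d",
          nodes$node_id, nodes$type_code, nodes$x, nodes$y, nodes$z,
          nodes$radius, nodes$parent_id)
}

#' Soma centroid of a skeleton
#'
#' The mean of the type-1 (soma) node coordinates; if no node is marked as
#' soma the root node position is used. Sholl shells are centred here.
#'
#' @param skel A `skeleton`.
#' @return Numeric length-3 vector (x, y, z) in micrometres.
#' @export
soma_center <- function(skel) {
  nodes <- skel$nodes
  soma <- nodes[nodes$type_code == 1L, , drop = FALSE]
  if (nrow(soma) == 0L)
    soma <- nodes[nodes$parent_id == -1L, , drop = FALSE]
  c(x = mean(soma$x), y = mean(soma$y), z = mean(soma$z))
}

# Parent-child segment table: one row per edge, with endpoint coordinates and
# a flag for intra-soma (type-1 to type-1) edges.
skeleton_segments <- function(skel) {
  nodes <- skel$nodes
  child <- nodes[nodes$parent_id != -1L, , drop = FALSE]
  if (nrow(child) == 0L) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
                      r1 = numeric(0), r2 = numeric(0),
                      intra_soma = logical(0)))
  }
  idx <- match(child$parent_id, nodes$node_id)
  parent <- nodes[idx, , drop = FALSE]
  data.frame(x1 = parent$x, y1 = parent$y, z1 = parent$z,
             x2 = child$x, y2 = child$y, z2 = child$z,
             r1 = parent$radius, r2 = child$radius,
             intra_soma = parent$type_code == 1L & child$type_code == 1L)
}
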