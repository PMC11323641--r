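# Independent oracles and small utilities shared across tests.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - e
  if (denom == 0) return(1)
  (sij - e) / denom
}

# Brute-force Sholl oracle: solves the segment-sphere quadratic per
# segment and counts a segment once if any intersection parameter lies in
# [0, 1].
sholl_oracle <- function(skel, step) {
  ctr <- soma_center(skel)
  nodes <- skel$nodes
  child <- nodes[nodes$parent_id != -1, ]
  par <- nodes[match(child$parent_id, nodes$node_id), ]
  keep <- !(par$type_code == 1 & child$type_code == 1)
  child <- child[keep, ]
  par <- par[keep, ]
  dmax_node <- max(sqrt((nodes$x - ctr[1])^2 + (nodes$y - ctr[2])^2 +
                          (nodes$z - ctr[3])^2))
  radii <- step * seq_len(ceiling(dmax_node / step))
  counts <- integer(length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    for (k in seq_len(nrow(child))) {
      p1 <- c(par$x[k], par$y[k], par$z[k]) - ctr
      v <- c(child$x[k], child$y[k], child$z[k]) - ctr - p1
      a <- sum(v * v)
      b <- 2 * sum(p1 * v)
      cc <- sum(p1 * p1) - r^2
      hit <- FALSE
      if (a == 0) {
        hit <- cc == 0
      } else {
        disc <- b^2 - 4 * a * cc
        if (disc >= 0) {
          ts <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
          hit <- any(ts >= 0 & ts <= 1)
        }
      }
      if (hit) counts[i] <- counts[i] + 1L
    }
  }
  list(radii = radii, counts = as.integer(counts))
}

# Branch-order labeling oracle: BFS assigning order 1 to branches leaving
# the soma and order + 1 at each multifurcation; returns the number of
# branches with order 1 or 2.
branch_order_oracle <- function(skel) {
  nodes <- skel$nodes
  kids_of <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  type_of <- stats::setNames(nodes$type_code, nodes$node_id)
  soma <- nodes$node_id[nodes$type_code == 1]
  if (length(soma) == 0) soma <- nodes$node_id[nodes$parent_id == -1]
  starts <- unlist(kids_of[as.character(soma)], use.names = FALSE)
  starts <- starts[type_of[as.character(starts)] != 1]
  count <- 0L
  queue <- lapply(starts, function(s) c(s, 1L))
  while (length(queue) > 0) {
    head <- queue[[1]]
    queue <- queue[-1]
    cur <- head[1]
    order <- head[2]
    if (order <= 2L) count <- count + 1L
    repeat {
      k <- kids_of[[as.character(cur)]]
      if (length(k) == 1) cur <- k else break
    }
    if (length(k) >= 2) {
      for (kk in k) queue[[length(queue) + 1]] <- c(kk, order + 1L)
    }
  }
  count
}

# Per-edge summation oracle for total cable length.
length_oracle <- function(skel) {
  nodes <- skel$nodes
  total <- 0
  for (i in seq_len(nrow(nodes))) {
    pid <- nodes$parent_id[i]
    if (pid == -1) next
    j <- which(nodes$node_id == pid)
    if (nodes$type_code[i] == 1 && nodes$type_code[j] == 1) next
    total <- total + sqrt((nodes$x[i] - nodes$x[j])^2 +
                            (nodes$y[i] - nodes$y[j])^2 +
                            (nodes$z[i] - nodes$z[j])^2)
  }
  total
}

# One-sided upper-tail p value for the t distribution by numeric
# integration of the density (independent of pt()).
t_tail_numeric <- function(t, df) {
  f <- function(x) (1 + x^2 / df)^(-(df + 1) / 2)
  const <- gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2))
  const * stats::integrate(f, t, Inf, rel.tol = 1e-10)$value
}

# A small hand-built Y-shaped skeleton: soma at origin, trunk 15 um along
# x, two daughters of 25 um each.
y_tree <- function() {
  nodes <- data.frame(
    node_id = 1:4, type_code = c(1L, 3L, 3L, 3L),
    x = c(0, 15, 15 + 25 * cos(pi / 6), 15 + 25 * cos(pi / 6)),
    y = c(0, 0, 25 * sin(pi / 6), -25 * sin(pi / 6)),
    z = 0, radius = c(5, 1, 1, 1), parent_id = c(-1L, 1L, 2L, 2L))
  skeleton("ytree", nodes)
}

# Deterministic three-row feature table inside all validation bounds.
tiny_feature_table <- function() {
  data.frame(
    cell_id = c("c1", "c2", "c3"), mouse_id = "m1",
    subpopulation = c("pial", "fibrous", "protoplasmic_lower"),
    condition = c("control", "TBI", "TBI"),
    zone = c("none", "none", "A1"),
    x_um = c(0, 100, 200), y_um = c(0, -50, 25),
    area_um2 = c(300, 350, 420),
    convex_hull_area_um2 = c(2000, 2100, 2500),
    perimeter_um = c(150, 160, 170),
    circularity = c(0.3, 0.25, 0.2),
    solidity = c(0.15, 0.17, 0.18),
    length_um = c(900, 950, 1100),
    branches12 = c(10L, 12L, 15L),
    thickness_um3 = c(3000, 3200, 4100),
    intersections = c(12L, 14L, 18L),
    radius_um = c(60, 62, 75),
    stringsAsFactors = FALSE)
}
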