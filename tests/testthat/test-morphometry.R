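test_that("branch counts follow the primary/secondary definition", {
  # root -> single tip, no bifurcation
  s <- parse_swc(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 1", "3 3 20 0 0 1 2"))
  expect_equal(branch_counts(s), 1L)
  # soma with 3 primaries, each bifurcating once into 2: 3 + 6
  nodes <- data.frame(node_id = 1L, type_code = 1L, x = 0, y = 0, z = 0,
                      radius = 5, parent_id = -1L)
  id <- 2L
  for (p in 1:3) {
    ang <- 2 * pi * p / 3
    nodes <- rbind(nodes, data.frame(node_id = id, type_code = 3L,
                                     x = 10 * cos(ang), y = 10 * sin(ang),
                                     z = 0, radius = 1, parent_id = 1L))
    tip <- id
    id <- id + 1L
    for (k in 1:2) {
      nodes <- rbind(nodes, data.frame(node_id = id, type_code = 3L,
                                       x = 20 * cos(ang + k / 4),
                                       y = 20 * sin(ang + k / 4),
                                       z = 0, radius = 1, parent_id = tip))
      id <- id + 1L
    }
  }
  expect_equal(branch_counts(skeleton("tri", nodes)), 9L)
  # soma-only skeleton
  solo <- skeleton("solo", nodes[1, ])
  expect_equal(branch_counts(solo), 0L)
})

test_that("branch counts match the branch-order labeling oracle on seeded trees", {
  for (s in 1:40) {
    sk <- simulate_skeleton(n_primary = 1 + s %% 5,
                            bifurcation_prob = (s %% 4) / 4,
                            segments_per_branch = 3, seed = s)
    expect_equal(branch_counts(sk), branch_order_oracle(sk))
  }
})

test_that("total length sums parent-child segments, excluding intra-soma", {
  s <- parse_swc(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 1"))
  expect_equal(total_length(s), 10)
  expect_equal(total_length(y_tree()), 65)
  soma2 <- parse_swc(c("1 1 0 0 0 5 -1", "2 1 4 0 0 5 1", "3 3 4 8 0 1 2"))
  expect_equal(total_length(soma2), 8)  # the 4-um soma-soma edge is excluded
  for (s in 1:25) {
    sk <- simulate_skeleton(n_primary = 2 + s %% 3, seed = s)
    expect_equal(total_length(sk), length_oracle(sk), tolerance = 1e-9)
  }
})

test_that("length and branch counts are invariant under re-indexing and rigid motion", {
  sk <- simulate_skeleton(n_primary = 4, bifurcation_prob = 0.5, seed = 7)
  # re-index nodes (preserving structure)
  nodes <- sk$nodes
  perm <- sample(900:999, nrow(nodes))
  map <- stats::setNames(perm, nodes$node_id)
  nodes$node_id <- unname(map[as.character(nodes$node_id)])
  nodes$parent_id <- ifelse(nodes$parent_id == -1L, -1L,
                            unname(map[as.character(nodes$parent_id)]))
  sk2 <- skeleton("perm", nodes[sample(nrow(nodes)), ])
  expect_equal(total_length(sk2), total_length(sk), tolerance = 1e-9)
  expect_equal(branch_counts(sk2), branch_counts(sk))
  # rigid rotation about z plus translation
  th <- 0.83
  rot <- sk$nodes
  xy <- cbind(rot$x, rot$y) %*% rbind(c(cos(th), sin(th)),
                                      c(-sin(th), cos(th)))
  rot$x <- xy[, 1] + 40
  rot$y <- xy[, 2] - 17
  rot$z <- rot$z + 5
  sk3 <- skeleton("rot", rot)
  expect_equal(total_length(sk3), total_length(sk), tolerance = 1e-9)
  expect_equal(branch_counts(sk3), branch_counts(sk))
})

test_that("coordinate scaling multiplies length by s and frustum volume by s^3", {
  sk <- simulate_skeleton(n_primary = 3, bifurcation_prob = 0.5, seed = 11)
  sc <- sk$nodes
  sc[, c("x", "y", "z", "radius")] <- sc[, c("x", "y", "z", "radius")] * 2.5
  sk2 <- skeleton("scaled", sc)
  expect_equal(total_length(sk2), 2.5 * total_length(sk), tolerance = 1e-9)
  expect_equal(thickness(sk2)$value, 2.5^3 * thickness(sk)$value,
               tolerance = 1e-9)
})

test_that("thickness: stack mode counts voxels above the relative threshold", {
  stack <- array(0, c(10, 10, 5))
  stack[1:4, 1:5, 1:5] <- 1       # 100 voxels at max
  stack[5, 1, 1] <- 0.04          # below 0.05 * max
  expect_equal(thickness(stack)$value, 100)
  expect_equal(thickness(stack, voxel_dims = c(0.5, 0.5, 2))$value, 50)
  expect_equal(thickness(stack)$mode, "stack")
  expect_error(thickness(array(0, c(3, 3, 3))), "all zero")
  # seeded stacks against a brute-force voxel scan
  for (s in 1:10) {
    set.seed(s)
    a <- array(stats::runif(8 * 8 * 8), c(8, 8, 8))
    oracle <- sum(a > 0.05 * max(a)) * 1.5^3
    expect_equal(thickness(a, voxel_dims = rep(1.5, 3))$value, oracle)
  }
})

test_that("thickness: skeleton fallback uses conical frusta", {
  cyl <- skeleton("cyl", data.frame(node_id = 1:2, type_code = c(1L, 3L),
                                    x = c(0, 10), y = 0, z = 0,
                                    radius = c(1, 1), parent_id = c(-1L, 1L)))
  res <- thickness(cyl)
  expect_equal(res$value, 10 * pi, tolerance = 1e-12)
  expect_equal(res$mode, "skeleton")
  zero <- skeleton("z0", data.frame(node_id = 1:2, type_code = c(1L, 3L),
                                    x = c(0, 10), y = 0, z = 0, radius = 0,
                                    parent_id = c(-1L, 1L)))
  expect_error(thickness(zero), "radii")
})

test_that("extract_features assembles all ten parameters with provenance", {
  mask <- simulate_mask("square", 10)
  rec <- extract_features(mask, y_tree(),
                          metadata = list(cell_id = "fix", mouse_id = "m9",
                                          subpopulation = "fibrous",
                                          condition = "TBI", zone = "A2"))
  expect_equal(rec$length_um, 65)
  expect_equal(rec$branches12, 3L)   # 1 primary + 2 secondaries
  expect_equal(rec$area_um2, 100, tolerance = 0.01)
  expect_equal(attr(rec, "thickness_mode"), "skeleton")
  expect_silent(validate_feature_table(rbind(rec)))
  expect_error(extract_features(NULL, y_tree(),
                                metadata = list(cell_id = "fix")), "fix")
  expect_error(extract_features(mask, NULL,
                                metadata = list(cell_id = "fix")), "fix")
})

test_that("synthetic cells produce records satisfying all invariants", {
  for (s in 1:30) {
    sk <- simulate_skeleton(n_primary = 2 + s %% 4, bifurcation_prob = 0.5,
                            seed = s, cell_id = paste0("cell", s))
    mask <- simulate_mask(c("disk", "star")[1 + s %% 2], 30 + s %% 20,
                          cell_id = paste0("cell", s))
    rec <- extract_features(mask, sk, metadata = list(cell_id = paste0("cell", s)))
    expect_silent(validate_feature_table(rbind(rec)))
  }
})
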