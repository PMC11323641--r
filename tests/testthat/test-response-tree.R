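test_that("cluster CIs are t-based with the right half-width", {
  z <- matrix(c(8, 10, 12, 5, 5, 5), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("perimeter", "length")))
  ci <- cluster_ci(z, rep("A", 3))
  row <- ci[ci$parameter == "perimeter", ]
  expect_equal(row$mean, 10)
  # half-width against numeric inversion of the t CDF
  alpha_tail <- function(q) t_tail_numeric(q, 2)
  q975 <- stats::uniroot(function(q) alpha_tail(q) - 0.025, c(2, 10),
                         tol = 1e-10)$root
  expect_equal(row$ci_high - row$mean, q975 * 2 / sqrt(3), tolerance = 1e-6)
  # constant cluster: zero width
  const <- ci[ci$parameter == "length", ]
  expect_equal(const$ci_low, const$ci_high)
  expect_warning(cluster_ci(z, c("A", "A", "B")), "singleton")
})

test_that("cluster CIs cover the generating mean at the nominal rate", {
  set.seed(61)
  covered <- replicate(1000, {
    v <- stats::rnorm(12, mean = 3, sd = 2)
    ci <- cluster_ci(matrix(v, ncol = 1, dimnames = list(NULL, "p")),
                     rep("A", 12))
    ci$ci_low <= 3 && 3 <= ci$ci_high
  })
  expect_lt(abs(mean(covered) - 0.95), 0.02)
})

test_that("two clusters with disjoint CIs split at the CI-gap midpoint", {
  # cluster means far apart with tiny spread: CIs ~ [1,2] and [5,6]
  v <- c(1.4, 1.5, 1.6, 5.4, 5.5, 5.6)
  z <- matrix(rep(v, 3), ncol = 3,
              dimnames = list(paste0("c", 1:6),
                              c("perimeter", "intersections", "radius")))
  labels <- rep(c("A", "B"), each = 3)
  tree <- build_response_tree(z, labels)
  expect_length(tree$cutoffs, 1L)
  ci <- cluster_ci(z[, 1, drop = FALSE], labels)
  expect_equal(tree$cutoffs,
               (ci$ci_high[ci$cluster == "A"] + ci$ci_low[ci$cluster == "B"]) / 2)
  # routing: below the cut-off goes to the lower leaf, ties go upper
  lower <- classify_cell(tree, c(perimeter = 2.9, intersections = 2.9,
                                 radius = 2.9))
  upper <- classify_cell(tree, stats::setNames(rep(tree$cutoffs, 3),
                                               colnames(z)))
  expect_false(identical(lower$path, upper$path))
  expect_equal(upper$path, paste0("response_score:2"))
})

test_that("single-cluster input yields a single-leaf tree", {
  set.seed(62)
  z <- matrix(stats::rnorm(30), 10, 3,
              dimnames = list(NULL, c("perimeter", "intersections", "radius")))
  tree <- build_response_tree(z, rep("A", 10))
  expect_length(tree$cutoffs, 0L)
  expect_length(tree$children, 1L)
  expect_equal(tree$children[[1]]$clusters, "A")
})

test_that("classification errors name the missing parameter", {
  p <- simulate_cluster_preset(seed = 63)
  tree <- build_response_tree(p$z, p$labels, category_map = p$category_map)
  expect_error(classify_cell(tree, c(length = 1)), "perimeter")
})

test_that("the designed eight-cluster structure reproduces the category tree", {
  ok_struct <- 0L
  ok_route <- 0L
  for (s in 1:15) {
    p <- simulate_cluster_preset(seed = s)
    tree <- build_response_tree(p$z, p$labels, category_map = p$category_map)
    cm <- tree_category_map(tree)
    struct <- length(tree$cutoffs) == 2 &&
      all(cm[c("C", "D")] == "moderate") &&
      all(cm[c("A", "B")] == "strong") &&
      all(cm[c("E", "F", "G", "H")] == "very_strong")
    if (struct) ok_struct <- ok_struct + 1L
    agree <- mean(classify_cells(tree, p$z)$category ==
                    p$category_map[p$labels])
    if (struct && agree >= 0.9) ok_route <- ok_route + 1L
  }
  expect_gte(ok_struct, 13L)
  expect_gte(ok_route, 13L)
})

test_that("sub-labels follow the documented vocabularies in interval order", {
  p <- simulate_cluster_preset(seed = 64)
  tree <- build_response_tree(p$z, p$labels, category_map = p$category_map)
  leaves <- list()
  walk <- function(node) {
    if (!is.null(node$category)) leaves[[length(leaves) + 1]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(unclass(tree))
  by_cluster <- function(cl) Filter(function(l) cl %in% l$clusters, leaves)[[1]]
  expect_equal(unname(by_cluster("A")$sublabels["convex_hull_area"]), "medium")
  expect_equal(unname(by_cluster("B")$sublabels["convex_hull_area"]), "large")
  expect_equal(unname(by_cluster("E")$sublabels["length"]), "short")
  expect_equal(unname(by_cluster("G")$sublabels["thickness"]), "medium")
  expect_equal(unname(by_cluster("H")$sublabels["thickness"]), "large")
})

test_that("tree construction is invariant to cluster label permutation", {
  p <- simulate_cluster_preset(seed = 65)
  relabel <- stats::setNames(rev(LETTERS[1:8]), LETTERS[1:8])
  cm2 <- stats::setNames(p$category_map, unname(relabel[names(p$category_map)]))
  t1 <- build_response_tree(p$z, p$labels, category_map = p$category_map)
  t2 <- build_response_tree(p$z, unname(relabel[p$labels]),
                            category_map = cm2)
  expect_equal(t1$cutoffs, t2$cutoffs)
  expect_identical(classify_cells(t1, p$z)$category,
                   classify_cells(t2, p$z)$category)
})

test_that("tree JSON serializes with cut-offs and leaves", {
  p <- simulate_cluster_preset(seed = 66)
  tree <- build_response_tree(p$z, p$labels, category_map = p$category_map)
  js <- response_tree_json(tree)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(parsed$parameter, "response_score")
  expect_length(parsed$children, 3L)
})

test_that("composition frequencies have closed margins", {
  comp <- composition_frequencies(rep("strong", 10), rep("pial", 10))
  expect_equal(comp$counts$n, 10L)
  expect_equal(comp$pct_within_category$pct, 100)
  set.seed(67)
  cats <- sample(c("moderate", "strong", "very_strong"), 120, replace = TRUE)
  subs <- sample(SUBPOPULATIONS, 120, replace = TRUE)
  comp2 <- composition_frequencies(cats, subs)
  sums <- tapply(comp2$pct_within_category$pct,
                 comp2$pct_within_category$category, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  sums2 <- tapply(comp2$pct_within_subpopulation$pct,
                  comp2$pct_within_subpopulation$subpopulation, sum)
  expect_true(all(abs(sums2 - 100) < 1e-9))
})

test_that("strong responses are enriched for protoplasmic cells on the study preset", {
  cfg <- load_config(overrides = list(seed = 5))
  rep5 <- run_pipeline(cfg)
  tab <- rep5$assignments
  tbi <- rep5$feature_table[rep5$feature_table$condition == "TBI", ]
  sub <- tbi$subpopulation[match(tab$cell_id, tbi$cell_id)]
  proto <- grepl("protoplasmic", sub)
  strong <- tab$category %in% c("strong", "very_strong")
  if (any(strong) && any(!strong)) {
    enrich <- mean(proto[strong]) / mean(proto)
    expect_gt(enrich, 0.8)
  }
  expect_true(all(tab$category %in% c("moderate", "strong", "very_strong")))
})
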