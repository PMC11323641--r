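#' Study design for the synthetic feature-table generator
#'
#' Encodes the per-stratum cell counts of the study (pial 15 TBI / 10
#' control; protoplasmic upper layers 19 A1 + 15 A2 / 10; protoplasmic
#' lower layers 13 A1 + 22 A2 / 10; juxtavascular 19 / 10; fibrous 15 /
#' 10; 118 TBI cells in total), the per-parameter baseline distributions
#' (lognormal for sizes and counts, logit-normal for the circularity and
#' solidity ratios) and the designed effects.
#'
#' Presets for `effects`:
#' * `"null"` - no effects anywhere (calibration runs);
#' * `"significance"` - standardized shifts of size `d` on 9 of 10
#'   parameters (all but thickness) in lower-layer contusion-core (A1)
#'   cells, and on radius only in upper-layer TBI cells;
#' * `"bimodal"` - two-component mixtures (separation `bimodal_delta`
#'   within-component sds, on the log / logit scale) in the six
#'   multimodal parameters (convex hull area, perimeter, length,
#'   thickness, intersections, radius) across all TBI cells;
#' * `"paper"` - both of the above (the full study emulation).
#'
#' @param effects Preset name (see above).
#' @param d Standardized effect size for the significance preset
#'   (default 2).
#' @param bimodal_delta Mixture separation in within-component sds
#'   (default 6).
#' @return A `study_design` list.
#' @export
study_design <- function(effects = c("paper", "null", "significance",
                                     "bimodal"),
                         d = 2, bimodal_delta = 6) {
  effects <- match.arg(effects)
  strata <- rbind(
    data.frame(subpopulation = "pial", condition = "TBI", zone = "none", n = 15),
    data.frame(subpopulation = "pial", condition = "control", zone = "none", n = 10),
    data.frame(subpopulation = "protoplasmic_upper", condition = "TBI", zone = "A1", n = 19),
    data.frame(subpopulation = "protoplasmic_upper", condition = "TBI", zone = "A2", n = 15),
    data.frame(subpopulation = "protoplasmic_upper", condition = "control", zone = "none", n = 10),
    data.frame(subpopulation = "protoplasmic_lower", condition = "TBI", zone = "A1", n = 13),
    data.frame(subpopulation = "protoplasmic_lower", condition = "TBI", zone = "A2", n = 22),
    data.frame(subpopulation = "protoplasmic_lower", condition = "control", zone = "none", n = 10),
    data.frame(subpopulation = "juxtavascular", condition = "TBI", zone = "none", n = 19),
    data.frame(subpopulation = "juxtavascular", condition = "control", zone = "none", n = 10),
    data.frame(subpopulation = "fibrous", condition = "TBI", zone = "none", n = 15),
    data.frame(subpopulation = "fibrous", condition = "control", zone = "none", n = 10))
  baselines <- data.frame(
    parameter = PARAMETER_NAMES,
    family = c("lognormal", "lognormal", "lognormal", "logitnormal",
               "logitnormal", "lognormal", "count", "lognormal",
               "count", "lognormal"),
    location = c(log(300), log(2000), log(150), stats::qlogis(0.25),
                 stats::qlogis(0.15), log(900), log(12), log(3000),
                 log(14), log(60)),
    scale = c(0.25, 0.25, 0.20, 0.40, 0.30, 0.25, 0.20, 0.35, 0.25, 0.20),
    stringsAsFactors = FALSE)
  effect_rows <- NULL
  if (effects %in% c("significance", "paper")) {
    lower9 <- setdiff(PARAMETER_NAMES, "thickness")
    sign9 <- ifelse(lower9 %in% c("circularity", "solidity"), -1, 1)
    effect_rows <- rbind(
      data.frame(subpopulation = "protoplasmic_lower", condition = "TBI",
                 zone = "A1", parameter = lower9, d = d * sign9),
      data.frame(subpopulation = "protoplasmic_upper", condition = "TBI",
                 zone = c("A1", "A2"), parameter = "radius", d = d))
  }
  bimodal_params <- if (effects %in% c("bimodal", "paper"))
    c("convex_hull_area", "perimeter", "length", "thickness",
      "intersections", "radius")
  else character(0)
  structure(list(strata = strata, baselines = baselines,
                 effects = effect_rows, bimodal_parameters = bimodal_params,
                 bimodal_delta = bimodal_delta, preset = effects),
            class = "study_design")
}

#' Simulate a per-cell feature table from a study design
#'
#' For each stratum, each parameter is drawn from its baseline family on
#' its natural scale (log for sizes and counts, logit for ratios). A
#' designed effect of standardized size `d` shifts the location by
#' `d * scale` on that scale. Bimodal parameters are equal-weight
#' two-component mixtures on the raw scale: half the TBI cells get an
#' offset of `bimodal_delta` baseline standard deviations, so both
#' components share the within-component sd. Count parameters are rounded
#' to integers, ratios stay inside (0, 1]. Deterministic for a given seed.
#'
#' @param design A `study_design`.
#' @param seed Integer seed (mandatory).
#' @return A validated feature table; cell positions place A1 cells within
#'   and A2 cells beyond 250 um of the section origin.
#' @export
simulate_feature_table <- function(design = study_design(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(design$strata))) {
    st <- design$strata[i, ]
    if (st$n == 0L) next
    feats <- matrix(NA_real_, nrow = st$n, ncol = length(PARAMETER_NAMES),
                    dimnames = list(NULL, PARAMETER_NAMES))
    # latent per-cell morphotype: the mixture component is shared across
    # the bimodal parameters (a hypertrophic cell is large throughout)
    cell_component <- sample(c(0, 1), st$n, replace = TRUE)
    for (j in seq_len(nrow(design$baselines))) {
      b <- design$baselines[j, ]
      d_eff <- 0
      if (!is.null(design$effects)) {
        hit <- design$effects$subpopulation == st$subpopulation &
          design$effects$condition == st$condition &
          design$effects$zone == st$zone &
          design$effects$parameter == b$parameter
        if (any(hit)) d_eff <- design$effects$d[hit][1L]
      }
      sd_raw <- exp(b$location + b$scale^2 / 2) * sqrt(exp(b$scale^2) - 1)
      loc <- b$location
      if (b$family == "logitnormal") loc <- loc + d_eff * b$scale
      raw <- stats::rnorm(st$n, loc, b$scale)
      vals <- switch(b$family,
        lognormal = exp(raw),
        count = exp(raw),
        logitnormal = stats::plogis(raw))
      # effects shift the mean by d baseline sds on the raw scale (ratio
      # parameters shift on their logit scale instead, keeping (0, 1])
      if (b$family != "logitnormal" && d_eff != 0)
        vals <- pmax(vals + d_eff * sd_raw, 0)
      if (st$condition == "TBI" && b$parameter %in% design$bimodal_parameters &&
          b$family %in% c("lognormal", "count")) {
        # population-level dichotomy: both mixture components shared
        # across strata, separated by bimodal_delta baseline sds
        vals <- vals + cell_component * design$bimodal_delta * sd_raw
      }
      if (b$family == "count") vals <- round(vals)
      feats[, b$parameter] <- vals
    }
    # positions: A1 within 250 um of the injury (origin), A2 at 250-1000 um,
    # unzoned cells spread over the section
    r <- switch(st$zone,
                A1 = stats::runif(st$n, 20, 240),
                A2 = stats::runif(st$n, 280, 900),
                none = stats::runif(st$n, 50, 1100))
    theta <- stats::runif(st$n, 0, 2 * pi)
    ids <- sprintf("cell%04d", counter + seq_len(st$n))
    counter <- counter + st$n
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = ids,
      mouse_id = if (st$condition == "TBI") "tbi1" else "ctrl1",
      subpopulation = st$subpopulation, condition = st$condition,
      zone = st$zone,
      x_um = r * cos(theta), y_um = r * sin(theta),
      area_um2 = feats[, "area"],
      convex_hull_area_um2 = pmax(feats[, "convex_hull_area"],
                                  feats[, "area"]),
      perimeter_um = feats[, "perimeter"],
      circularity = feats[, "circularity"],
      solidity = feats[, "solidity"],
      length_um = feats[, "length"],
      branches12 = pmax(feats[, "branches12"], 0),
      thickness_um3 = feats[, "thickness"],
      intersections = pmax(feats[, "intersections"], 0),
      radius_um = feats[, "radius"],
      stringsAsFactors = FALSE)
  }
  validate_feature_table(do.call(rbind, rows))
}

#' Simulate a branched skeleton
#'
#' Grows a rooted tree outward from a soma node: `n_primary` primary
#' branches leave the soma in random directions; each branch is a run of
#' segments with lognormal lengths and small angular jitter, and at its
#' end bifurcates into two daughters with probability `bifurcation_prob`
#' while below `max_order`. Deterministic per seed.
#'
#' @param n_primary Number of primary branches (>= 1).
#' @param bifurcation_prob Probability that a branch end bifurcates.
#' @param segments_per_branch Segments per branch run (default 4).
#' @param mean_segment_length Mean segment length, um (default 8).
#' @param max_order Maximum branch order (default 3).
#' @param soma_radius Soma node radius, um.
#' @param seed Integer seed.
#' @param cell_id Cell identifier.
#' @return A validated `skeleton`.
#' @export
simulate_skeleton <- function(n_primary = 5, bifurcation_prob = 0.4,
                              segments_per_branch = 4,
                              mean_segment_length = 8, max_order = 3,
                              soma_radius = 5, seed, cell_id = "sim") {
  if (n_primary < 1L) stop("n_primary must be >= 1")
  if (!missing(seed)) set.seed(seed)
  nodes <- data.frame(node_id = 1L, type_code = 1L, x = 0, y = 0, z = 0,
                      radius = soma_radius, parent_id = -1L)
  next_id <- 2L
  rand_dir <- function() {
    v <- stats::rnorm(3L)
    v / sqrt(sum(v^2))
  }
  grow <- function(parent_id, pos, dir, order) {
    for (s in seq_len(segments_per_branch)) {
      len <- stats::rlnorm(1L, log(mean_segment_length), 0.3)
      dir <- dir + stats::rnorm(3L, sd = 0.15)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + len * dir
      nodes[nrow(nodes) + 1L, ] <<- list(next_id, 3L, pos[1L], pos[2L],
                                         pos[3L], soma_radius / (order + 1),
                                         parent_id)
      parent_id <- next_id
      next_id <<- next_id + 1L
    }
    if (order < max_order && stats::runif(1L) < bifurcation_prob) {
      for (k in 1:2) {
        child_dir <- dir + stats::rnorm(3L, sd = 0.6)
        grow(parent_id, pos, child_dir / sqrt(sum(child_dir^2)), order + 1L)
      }
    }
  }
  for (p in seq_len(n_primary)) grow(1L, c(0, 0, 0), rand_dir(), 1L)
  skeleton(cell_id, nodes)
}

#' Simulate a rasterized cell mask with its exact generating polygon
#'
#' Shapes: a disk, a square, or a k-armed star with the given inner/outer
#' radius ratio. The exact generating polygon (in micrometres; a fine
#' 720-gon for the disk) is attached as attribute `polygon` for
#' exact-geometry oracle comparisons.
#'
#' @param shape `"disk"`, `"square"` or `"star"`.
#' @param size Radius (disk, star outer) or side (square), in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param k_arms Star arm count (default 5).
#' @param inner_ratio Star inner/outer radius ratio (default 0.45).
#' @param margin Background margin in pixels around the shape.
#' @param cell_id Cell identifier.
#' @return A `cell_mask` with attribute `polygon`.
#' @export
simulate_mask <- function(shape = c("disk", "square", "star"), size = 50,
                          pixel_size = 1, k_arms = 5, inner_ratio = 0.45,
                          margin = 5, cell_id = "sim") {
  shape <- match.arg(shape)
  if (shape == "square") {
    n_px <- round(size) + 2L * margin
    grid <- matrix(FALSE, n_px, n_px)
    grid[(margin + 1L):(margin + round(size)),
         (margin + 1L):(margin + round(size))] <- TRUE
    side <- round(size) * pixel_size
    off <- margin * pixel_size
    poly <- cbind(c(off, off + side, off + side, off),
                  c(off, off, off + side, off + side))
  } else {
    n_px <- 2L * (ceiling(size) + margin)
    ctr <- n_px / 2
    xs <- (seq_len(n_px) - 0.5)
    if (shape == "disk") {
      grid <- outer(xs - ctr, xs - ctr,
                    function(a, b) a^2 + b^2 <= size^2)
      th <- seq(0, 2 * pi, length.out = 721L)[-721L]
      poly <- cbind(ctr + size * cos(th), ctr + size * sin(th)) * pixel_size
    } else {
      th <- (seq_len(2L * k_arms) - 1L) * pi / k_arms - pi / 2
      rr <- rep(c(size, size * inner_ratio), k_arms)
      vx <- ctr + rr * cos(th)
      vy <- ctr + rr * sin(th)
      grid <- matrix(point_in_polygon(rep(xs, times = n_px),
                                      rep(xs, each = n_px), vx, vy),
                     n_px, n_px)
      poly <- cbind(vx, vy) * pixel_size
    }
  }
  m <- cell_mask(grid, pixel_size, cell_id)
  attr(m, "polygon") <- poly
  m
}

# Even-odd crossing-number point-in-polygon test (vectorized over points).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Simulate a GFAP intensity profile around an injury
#'
#' Step mode: an elevated plateau of height `contrast` above `baseline`
#' within `boundary_um` of the injury, over a `max_distance` range, plus
#' Gaussian bin noise. Decay mode: `contrast * exp(-d / decay_um) +
#' baseline` plus noise.
#'
#' @param boundary_um Plateau extent (default 250).
#' @param contrast Elevation above baseline (default 5).
#' @param baseline Distal intensity (default 1).
#' @param noise_sd Gaussian noise sd per bin (default 0.1).
#' @param bin_width Bin width, um (default 10).
#' @param max_distance Range, um (default 1000).
#' @param mode `"step"` or `"decay"`.
#' @param decay_um Decay length for decay mode, um (default 10: a sharp
#'   gliosis border relative to the 10 um bins).
#' @param seed Integer seed.
#' @return An `intensity_profile`.
#' @export
simulate_gfap_profile <- function(boundary_um = 250, contrast = 5,
                                  baseline = 1, noise_sd = 0.1,
                                  bin_width = 10, max_distance = 1000,
                                  mode = c("step", "decay"), decay_um = 10,
                                  seed) {
  mode <- match.arg(mode)
  if (!missing(seed)) set.seed(seed)
  centers <- seq(bin_width / 2, max_distance - bin_width / 2, by = bin_width)
  signal <- switch(mode,
                   step = baseline + contrast * (centers <= boundary_um),
                   decay = baseline + contrast * exp(-centers / decay_um))
  y <- pmax(signal + stats::rnorm(length(centers), sd = noise_sd), 0)
  new_intensity_profile(centers, y, bin_width)
}

#' Simulate a clone table
#'
#' Draws `n_clones` distinct 12-bit barcodes (each with at least one mark),
#' partitions `n_cells` cells over them, scatters each clone's members
#' around a uniform random centre with isotropic Gaussian spread, and
#' assigns each clone a subpopulation with protoplasmic lineages most
#' prevalent. Defaults mirror the study's 281 cells in 35 clones.
#'
#' @param n_clones Number of clones (default 35).
#' @param n_cells Total cells (default 281).
#' @param spatial_sd Member scatter around the clone centre, um
#'   (default 50).
#' @param field_um Side of the square field holding clone centres
#'   (default 1000).
#' @param seed Integer seed (mandatory).
#' @return data.frame: `cell_id`, the 12 code columns, `x_um`, `y_um`,
#'   `subpopulation`, plus the generating `true_clone` index.
#' @export
simulate_clones <- function(n_clones = 35, n_cells = 281, spatial_sd = 50,
                            field_um = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_cells < n_clones) stop("need at least one cell per clone")
  set.seed(seed)
  codes <- character(0)
  while (length(codes) < n_clones) {
    c12 <- paste(stats::rbinom(12L, 1L, 0.35), collapse = "")
    if (c12 != paste(rep("0", 12L), collapse = "") && !(c12 %in% codes))
      codes <- c(codes, c12)
  }
  extra <- stats::rmultinom(1L, n_cells - n_clones,
                            prob = stats::rlnorm(n_clones, 0, 1))[, 1L]
  sizes <- 1L + extra
  subpop_weights <- c(pial = 0.08, protoplasmic_upper = 0.30,
                      protoplasmic_lower = 0.30, juxtavascular = 0.12,
                      fibrous = 0.20)
  rows <- list()
  counter <- 0L
  for (cl in seq_len(n_clones)) {
    ctr <- stats::runif(2L, 0, field_um)
    bits <- as.integer(strsplit(codes[cl], "")[[1L]])
    code_df <- as.data.frame(as.list(stats::setNames(bits, CODE_COLUMNS)))
    sub <- sample(names(subpop_weights), 1L, prob = subpop_weights)
    for (m in seq_len(sizes[cl])) {
      counter <- counter + 1L
      rows[[counter]] <- cbind(
        data.frame(cell_id = sprintf("ccell%04d", counter)), code_df,
        data.frame(x_um = stats::rnorm(1L, ctr[1L], spatial_sd),
                   y_um = stats::rnorm(1L, ctr[2L], spatial_sd),
                   subpopulation = sub, true_clone = cl,
                   stringsAsFactors = FALSE))
    }
  }
  do.call(rbind, rows)
}

#' Simulate the eight-cluster reference structure in z-space
#'
#' Generates z-scored feature vectors for eight morphotype clusters A-H
#' over the six multimodal parameters, designed so that A+B and C+D
#' overlap pairwise (and E-H mutually) on the first-level response score
#' while the three groups separate; A and B separate on convex hull area;
#' E-H separate on length into E, F and G+H; and G and H separate on
#' thickness. Cluster sizes descend from A to H so size-ordered labels
#' coincide with the design.
#'
#' @param seed Integer seed (mandatory).
#' @param within_sd Within-cluster sd per feature (default 0.35).
#' @return List with `z` (cells x 6 matrix), `labels` (A-H), and
#'   `category_map`.
#' @export
simulate_cluster_preset <- function(seed, within_sd = 0.35) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  sizes <- c(A = 25, B = 22, C = 18, D = 16, E = 14, F = 13, G = 12, H = 11)
  score <- c(A = 0, B = 0.03, C = -1.10, D = -1.07,
             E = 1.20, F = 1.23, G = 1.26, H = 1.29)
  hull <- c(A = -0.8, B = 0.8, C = 0, D = 0, E = 0, F = 0, G = 0, H = 0)
  len <- c(A = 0, B = 0, C = 0, D = 0, E = -1.5, F = 0, G = 1.2, H = 1.26)
  thick <- c(A = 0, B = 0, C = 0, D = 0, E = 0, F = 0, G = -0.8, H = 0.8)
  params <- c("convex_hull_area", "perimeter", "length", "thickness",
              "intersections", "radius")
  labels <- rep(names(sizes), sizes)
  n <- length(labels)
  z <- matrix(stats::rnorm(n * length(params), sd = within_sd), nrow = n,
              dimnames = list(sprintf("pcell%03d", seq_len(n)), params))
  z[, "perimeter"] <- z[, "perimeter"] + score[labels]
  z[, "intersections"] <- z[, "intersections"] + score[labels]
  z[, "radius"] <- z[, "radius"] + score[labels]
  z[, "convex_hull_area"] <- z[, "convex_hull_area"] + hull[labels]
  z[, "length"] <- z[, "length"] + len[labels]
  z[, "thickness"] <- z[, "thickness"] + thick[labels]
  list(z = z, labels = labels,
       category_map = c(A = "strong", B = "strong", C = "moderate",
                        D = "moderate", E = "very_strong", F = "very_strong",
                        G = "very_strong", H = "very_strong"))
}

#' Simulate well-separated morphotype blobs in feature space
#'
#' `k` isotropic Gaussian blobs of `n_per` cells in `p` dimensions whose
#' centres are `separation` within-blob sds apart along orthogonal axes.
#'
#' @param k Number of blobs (default 3).
#' @param n_per Cells per blob (default 30).
#' @param p Feature dimension (default 6).
#' @param separation Centre separation in within-blob sds (default 10).
#' @param seed Integer seed (mandatory).
#' @return List with `x` (matrix) and `labels` (integer blob index).
#' @export
simulate_blobs <- function(k = 3, n_per = 30, p = 6, separation = 10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  centers <- matrix(0, k, p)
  for (i in seq_len(k)) centers[i, ((i - 1L) %% p) + 1L] <- (i - 1L) * separation
  labels <- rep(seq_len(k), each = n_per)
  x <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(k * n_per * p), ncol = p)
  rownames(x) <- sprintf("bcell%03d", seq_along(labels))
  list(x = x, labels = labels)
}
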