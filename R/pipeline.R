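#' Run the full morphometric classification pipeline
#'
#' Orchestrates the stages end to end on a feature table (by default a
#' synthetic table emulating the study design): lesion-profile zoning,
#' coefficient-of-variation screening, the per-subpopulation significance
#' screen, multimodal-index parameter selection, z-score normalization,
#' hierarchical clustering, PCA, t-SNE plus HDBSCAN, per-cluster
#' confidence intervals, the response-category logical tree, composition
#' frequencies, and clonal statistics. All randomness flows from the
#' configured master seed (split per stage), so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param config Configuration list from [load_config()] /
#'   [default_config()].
#' @param table Optional feature table; when `NULL` a synthetic table is
#'   generated from [study_design()] preset `"paper"` under the master
#'   seed.
#' @param clone_table Optional clone table; when `NULL` a synthetic
#'   35-clone / 281-cell table is generated.
#' @param verbose Log resolved parameters and stage row counts.
#' @return A `pipeline_report` list with the stage outputs, the resolved
#'   config, and a `report_hash` over all result tables.
#' @export
run_pipeline <- function(config = load_config(), table = NULL,
                         clone_table = NULL, verbose = FALSE) {
  log_msg <- function(...) if (verbose) message("[astromorph] ", ...)
  seed <- as.integer(config$seed)
  stage_seed <- function(k) seed + 1000L * k
  log_msg("config hash ", substr(config_hash(config), 1, 12),
          "; master seed ", seed)

  if (is.null(table)) {
    table <- simulate_feature_table(study_design("paper"),
                                    seed = stage_seed(1L))
    log_msg("simulated feature table: ", nrow(table), " cells")
  }
  table <- validate_feature_table(table)

  # lesion zoning on the GFAP profile (checked against the cell zone labels)
  profile <- simulate_gfap_profile(seed = stage_seed(2L))
  boundary <- if (is.finite(config$zone_boundary_override)) {
    structure(list(boundary_distance = config$zone_boundary_override,
                   no_a1 = FALSE, baseline = NA, mad = NA,
                   k = NA, run = NA,
                   max_distance = config$zone_max_distance),
              class = "zone_boundary")
  } else {
    delineate_areas(profile, k = config$zone_k, run = config$zone_run,
                    smooth = config$zone_smooth)
  }
  log_msg("A1/A2 boundary at ", round(boundary$boundary_distance), " um")

  cv_table <- cv_radar_table(table)
  screen <- significance_screen(table, tail = config$test_tail)

  sel <- select_parameters(table, threshold = config$mmi_threshold,
                           population = config$mmi_population)
  log_msg("MMI selected: ", paste(sel$selected, collapse = ", "))

  tbi <- table[table$condition == "TBI", , drop = FALSE]
  z <- zscore_normalize(tbi, sel$selected)

  hc <- hierarchical_cluster(z, distance_threshold = config$hc_threshold,
                             linkage = config$hc_linkage,
                             k = if (is.finite(config$hc_k)) config$hc_k else NULL)
  pca <- pca_features(z)
  tsne <- tsne_embed(z, perplexity = config$tsne_perplexity,
                     seed = stage_seed(3L))
  hdb <- hdbscan_cluster(tsne$embedding,
                         min_cluster_size = config$hdbscan_min_cluster_size)
  log_msg("HC clusters: ", hc$k, "; HDBSCAN clusters: ", hdb$n_clusters)

  ci_table <- withCallingHandlers(
    cluster_ci(z, hc$labels, level = config$ci_level),
    warning = function(w) invokeRestart("muffleWarning"))
  tree <- withCallingHandlers(
    build_response_tree(z, hc$labels, level = config$ci_level),
    warning = function(w) invokeRestart("muffleWarning"))
  classified <- classify_cells(tree, z)
  comp <- composition_frequencies(
    classified$category,
    tbi$subpopulation[match(classified$cell_id, tbi$cell_id)])

  if (is.null(clone_table))
    clone_table <- simulate_clones(seed = stage_seed(4L))
  clones <- group_clones(clone_table)
  clone_stats <- clone_statistics(clones)

  assignments <- data.frame(
    cell_id = rownames(z),
    hc_label = unname(hc$labels[rownames(z)]),
    hdbscan_label = unname(hdb$labels[rownames(z)]),
    tsne_x = tsne$embedding[, 1L], tsne_y = tsne$embedding[, 2L],
    pc1 = pca$scores[, 1L],
    pc2 = if (ncol(pca$scores) >= 2L) pca$scores[, 2L] else NA_real_,
    category = classified$category[match(rownames(z), classified$cell_id)],
    stringsAsFactors = FALSE)
  rownames(assignments) <- NULL

  report <- list(
    config = config,
    seed = seed,
    feature_table = table,
    boundary = boundary,
    cv_table = cv_table,
    significance = screen,
    mmi = sel$mmi_table,
    selected_parameters = sel$selected,
    pca_explained = pca$explained,
    pca_loadings = pca$loadings,
    assignments = assignments,
    cluster_ci = ci_table,
    tree = tree,
    composition = comp,
    clone_statistics = clone_stats)
  report$report_hash <- report_hash(report)
  class(report) <- "pipeline_report"
  report
}

#' Hash the result tables of a pipeline report
#'
#' A digest over the serialized result tables (excluding the hash itself);
#' identical config + seed must reproduce it exactly.
#'
#' @param report A `pipeline_report` (or compatible list).
#' @return Character sha256 digest.
#' @export
report_hash <- function(report) {
  parts <- report[setdiff(names(report), c("report_hash", "tree"))]
  parts$tree_json <- as.character(response_tree_json(report$tree))
  digest::digest(lapply(parts, function(x) {
    if (is.data.frame(x)) lapply(x, unname) else x
  }), algo = "sha256")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  cells:", nrow(x$feature_table), " (",
      sum(x$feature_table$condition == "TBI"), "TBI )\n")
  cat("  selected parameters:", paste(x$selected_parameters, collapse = ", "), "\n")
  cat("  HC clusters:", length(setdiff(unique(x$assignments$hc_label), "noise")),
      "; PC1+PC2 explained:",
      sprintf("%.1f%%", 100 * sum(x$pca_explained[1:min(2, length(x$pca_explained))])), "\n")
  cat("  report hash:", substr(x$report_hash, 1, 16), "\n")
  invisible(x)
}
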