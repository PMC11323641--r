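#' Default pipeline configuration
#'
#' Stage parameters with their defaults: multimodal-index threshold 0.55,
#' hierarchical-clustering Euclidean distance threshold 2.3 (complete
#' linkage), t-SNE perplexity 5, HDBSCAN minimum cluster size 10, confidence
#' level 0.95, Sholl step 2 um, lesion-profile settings (1000 um range,
#' 10 um bins, k = 2 MADs, persistence 3 bins, 3-bin smoothing), and the
#' master seed.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    mmi_threshold = 0.55,
    mmi_population = "TBI",        # cells used for the multimodal index
    hc_threshold = 2.3,
    hc_linkage = "complete",
    hc_k = NA_integer_,            # alternative: cut to a fixed cluster count
    tsne_perplexity = 5,
    hdbscan_min_cluster_size = 10,
    ci_level = 0.95,
    sholl_step = 2,
    peak_fraction = 0.9,
    zone_max_distance = 1000,
    zone_bin_width = 10,
    zone_k = 2,
    zone_run = 3,
    zone_smooth = 3,
    zone_boundary_override = NA_real_,  # manual A1/A2 boundary, um
    radius_feature = "enclosing",  # or "critical"
    test_tail = "two.sided",       # default tail when no direction is given
    seed = 0
  )
}

#' Load and resolve a pipeline configuration
#'
#' Reads an optional YAML-style `key: value` file and merges it over the
#' documented defaults. Unknown keys and out-of-range values are errors
#' (fail closed). An empty or absent file yields all defaults.
#'
#' @param path Optional path to a configuration file.
#' @param overrides Optional named list applied after the file.
#' @return Resolved configuration list with attribute `hash` (stable across
#'   key order permutations).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1L]]
      if (length(kv) < 2L) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1L])
      val <- trimws(paste(kv[-1L], collapse = ":"))
      num <- suppressWarnings(as.numeric(val))
      user[[key]] <- if (!is.na(num)) num else val
    }
  }
  user[names(overrides)] <- overrides
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("hc_threshold", "tsne_perplexity", "sholl_step",
           "zone_max_distance", "zone_bin_width")
  for (k in pos) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
    stop("config '", k, "' must be > 0")
  if (cfg$mmi_threshold <= 0) stop("config 'mmi_threshold' must be > 0")
  if (cfg$hdbscan_min_cluster_size < 2)
    stop("config 'hdbscan_min_cluster_size' must be >= 2")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("config 'ci_level' must be in (0, 1)")
  if (cfg$peak_fraction <= 0 || cfg$peak_fraction > 1)
    stop("config 'peak_fraction' must be in (0, 1]")
  if (!cfg$hc_linkage %in% c("complete", "average", "ward.D2", "single"))
    stop("config 'hc_linkage' must be one of complete/average/ward.D2/single")
  if (!cfg$test_tail %in% c("two.sided", "less", "greater"))
    stop("config 'test_tail' must be two.sided/less/greater")
  invisible(cfg)
}

#' Stable hash of a resolved configuration
#' @param cfg Configuration list.
#' @return Character hash, invariant to key order.
#' @export
config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  attr(cfg, "hash") <- NULL
  digest::digest(cfg, algo = "sha256")
}
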