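#' GFAP intensity profile around an injury site
#'
#' Bins pixel intensities of a 2D image by Euclidean distance (in the
#' section plane) from the injury point, and returns the per-bin mean
#' intensity. Bins with no pixels are reported as `NA`, never as zero.
#'
#' @param image Numeric matrix of intensities.
#' @param injury_point Length-2 vector (x, y) in micrometres; must fall
#'   inside the image.
#' @param pixel_size Micrometres per pixel.
#' @param max_distance Profile range in micrometres (default 1000).
#' @param bin_width Bin width in micrometres (default 10).
#' @return An object of class `intensity_profile`: list with `bin_centers`,
#'   `mean_intensity`, `bin_width`, `injury_point`.
#' @export
intensity_profile <- function(image, injury_point, pixel_size = 1,
                              max_distance = 1000, bin_width = 10) {
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  xs <- (seq_len(nrow(image)) - 0.5) * pixel_size
  ys <- (seq_len(ncol(image)) - 0.5) * pixel_size
  if (injury_point[1L] < 0 || injury_point[1L] > nrow(image) * pixel_size ||
      injury_point[2L] < 0 || injury_point[2L] > ncol(image) * pixel_size)
    stop("injury_point lies outside the image")
  dx <- outer(xs - injury_point[1L], rep(1, ncol(image)))
  dy <- outer(rep(1, nrow(image)), ys - injury_point[2L])
  d <- sqrt(dx^2 + dy^2)
  edges <- seq(0, max_distance, by = bin_width)
  idx <- findInterval(d, edges, rightmost.closed = FALSE)
  keep <- d < max_distance
  means <- rep(NA_real_, length(edges) - 1L)
  agg <- tapply(image[keep], idx[keep], mean)
  means[as.integer(names(agg))] <- agg
  new_intensity_profile(edges[-length(edges)] + bin_width / 2, means,
                        bin_width, injury_point)
}

new_intensity_profile <- function(bin_centers, mean_intensity, bin_width,
                                  injury_point = c(0, 0)) {
  if (any(mean_intensity < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  structure(list(bin_centers = bin_centers,
                 mean_intensity = mean_intensity,
                 bin_width = bin_width,
                 injury_point = injury_point),
            class = "intensity_profile")
}

#' Read a precomputed distance-binned intensity profile CSV
#'
#' Expects columns `distance_um` (bin centres, contiguous and increasing)
#' and `intensity`.
#'
#' @param path CSV file path.
#' @param injury_point Injury coordinate to attach (default origin).
#' @return An `intensity_profile`.
#' @export
read_intensity_profile <- function(path, injury_point = c(0, 0)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("distance_um", "intensity") %in% names(tab)))
    stop("profile CSV needs columns distance_um, intensity")
  d <- diff(tab$distance_um)
  if (any(d <= 0)) stop("distance_um must be strictly increasing")
  new_intensity_profile(tab$distance_um, tab$intensity, d[1L], injury_point)
}

#' Delineate the contusion core (A1) from pericontusional tissue (A2)
#'
#' The baseline is the median intensity over the distal half of the profile
#' and its scale the MAD. Scanning outward from the injury, a bin is
#' "elevated" when the smoothed intensity (moving mean over `smooth` bins)
#' exceeds baseline + k*MAD. The A1/A2 boundary is placed at the left edge
#' of the first bin of the first run of `run` consecutive non-elevated
#' bins, i.e. the midpoint between the last elevated and first non-elevated
#' smoothed bin centres. If no bin is ever elevated the profile is flat and
#' an explicit "no A1" outcome is returned.
#'
#' @param profile An `intensity_profile` with at least 10 bins.
#' @param k MAD multiplier (default 2).
#' @param run Persistence: consecutive non-elevated bins required
#'   (default 3).
#' @param smooth Moving-mean window in bins (default 3).
#' @return An object of class `zone_boundary`: list with
#'   `boundary_distance` (um, `NA` when no A1 is detected), `no_a1` flag,
#'   `baseline`, `mad`, `k`, `run`, `max_distance`.
#' @export
delineate_areas <- function(profile, k = 2, run = 3, smooth = 3) {
  y <- profile$mean_intensity
  x <- profile$bin_centers
  if (length(y) < 10L) stop("profile needs at least 10 bins")
  ok <- is.finite(y)
  y <- y[ok]; x <- x[ok]
  distal <- y[seq.int(ceiling(length(y) / 2), length(y))]
  baseline <- stats::median(distal)
  scale_mad <- stats::mad(distal, center = baseline)
  thr <- baseline + k * scale_mad
  ys <- moving_mean(y, smooth)
  elevated <- ys > thr
  max_distance <- x[length(x)] + profile$bin_width / 2
  res <- function(boundary, no_a1) structure(
    list(boundary_distance = boundary, no_a1 = no_a1, baseline = baseline,
         mad = scale_mad, k = k, run = run, max_distance = max_distance),
    class = "zone_boundary")
  if (!any(elevated) || !elevated[1L]) return(res(NA_real_, TRUE))
  below_run <- 0L
  for (i in seq_along(elevated)) {
    if (!elevated[i]) {
      below_run <- below_run + 1L
      if (below_run == run) {
        first_below <- i - run + 1L
        return(res(x[first_below] - profile$bin_width / 2, FALSE))
      }
    } else below_run <- 0L
  }
  # elevated through the whole range: A1 spans the full profile
  res(max_distance, FALSE)
}

moving_mean <- function(y, w) {
  if (w <= 1L) return(y)
  half <- (w - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - half):min(n, i + half)])
  }, 0)
}

#' Assign a cell to a lesion zone
#'
#' Distance from the injury at or below the boundary is A1; between the
#' boundary and the profile range is A2; beyond the range (or when no A1
#' was detected) is "none".
#'
#' @param position Length-2 (x, y) in um, or a 2-column matrix of positions.
#' @param boundary A `zone_boundary` from [delineate_areas()].
#' @param injury_point Length-2 injury coordinate (um).
#' @return Character vector of zone labels in `{A1, A2, none}`.
#' @export
assign_zone <- function(position, boundary, injury_point = c(0, 0)) {
  pos <- if (is.null(dim(position))) matrix(position, ncol = 2L) else as.matrix(position)
  d <- sqrt((pos[, 1L] - injury_point[1L])^2 + (pos[, 2L] - injury_point[2L])^2)
  if (isTRUE(boundary$no_a1))
    return(ifelse(d <= boundary$max_distance, "A2", "none"))
  ifelse(d <= boundary$boundary_distance, "A1",
         ifelse(d <= boundary$max_distance, "A2", "none"))
}
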