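#' Cell mask objects
#'
#' A `cell_mask` is a 2D binary grid with a pixel size in micrometres per
#' pixel, the substrate for the 2D size- and shape-related parameters (area,
#' perimeter, convex hull area, circularity, solidity). Per-cell metrics
#' require exactly one 8-connected foreground component.
#'
#' @param grid Logical or 0/1 numeric matrix; `TRUE`/1 is foreground.
#' @param pixel_size Micrometres per pixel, > 0.
#' @param cell_id Cell identifier.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(grid, pixel_size, cell_id = "cell") {
  grid <- matrix(as.logical(grid), nrow = nrow(grid))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  if (!any(grid))
    stop("cell mask for '", cell_id, "' has no foreground pixel")
  structure(list(grid = grid, pixel_size = pixel_size,
                 cell_id = as.character(cell_id)),
            class = "cell_mask")
}

# 8-connected component count of a binary matrix (two-pass flood fill).
count_components8 <- function(grid) {
  lab <- matrix(0L, nrow(grid), ncol(grid))
  comp <- 0L
  nr <- nrow(grid); nc <- ncol(grid)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (grid[i, j] && lab[i, j] == 0L) {
      comp <- comp + 1L
      stack <- list(c(i, j))
      lab[i, j] <- comp
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1L] + di; jj <- p[2L] + dj
          if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
              grid[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- comp
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  comp
}

# --- exact polygon geometry (also the oracle path for rasterized shapes) ---

#' Shoelace area of a simple polygon
#'
#' @param xy Two-column matrix of vertices (closed or open ring).
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(xy) {
  xy <- close_ring(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- nrow(xy)
  abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
}

#' Perimeter of a polygon ring
#' @param xy Two-column matrix of vertices.
#' @return Total edge length.
#' @export
polygon_perimeter <- function(xy) {
  xy <- close_ring(xy)
  sum(sqrt(rowSums(diff(xy)^2)))
}

close_ring <- function(xy) {
  xy <- as.matrix(xy)
  if (!isTRUE(all.equal(xy[1L, ], xy[nrow(xy), ], check.attributes = FALSE)))
    xy <- rbind(xy, xy[1L, ])
  xy
}

#' Shape metrics of an exact polygon
#'
#' Computes area, perimeter, convex hull area, circularity
#' (4*pi*area/perimeter^2) and solidity (area / convex hull area) directly
#' from polygon vertices, with no rasterization. Used both for analytic
#' fixtures and as the exact-geometry oracle for rasterized masks.
#'
#' @param xy Two-column matrix of polygon vertices, in micrometres.
#' @return A list with `area`, `perimeter`, `convex_hull_area`,
#'   `circularity`, `solidity`.
#' @export
polygon_shape_features <- function(xy) {
  xy <- as.matrix(xy)
  a <- polygon_area(xy)
  p <- polygon_perimeter(xy)
  hull <- xy[grDevices::chull(xy[, 1L], xy[, 2L]), , drop = FALSE]
  h <- polygon_area(hull)
  list(area = a, perimeter = p, convex_hull_area = h,
       circularity = 4 * pi * a / p^2, solidity = a / h)
}

# Marching-squares boundary polygon of a binary mask, in micrometre
# coordinates. Pixel centres sit at (i - 0.5) * pixel_size; the mask is
# zero-padded so the 0.5-level contour closes around the cell. Returns the
# contour with the largest enclosed area (outer boundary).
mask_contour <- function(mask) {
  g <- mask$grid
  px <- mask$pixel_size
  padded <- matrix(0, nrow(g) + 2L, ncol(g) + 2L)
  padded[2:(nrow(g) + 1L), 2:(ncol(g) + 1L)] <- g * 1
  xs <- (seq_len(nrow(padded)) - 1.5) * px   # pixel-centre coordinates
  ys <- (seq_len(ncol(padded)) - 1.5) * px
  cl <- grDevices::contourLines(xs, ys, padded, levels = 0.5)
  if (length(cl) == 0L)
    stop("mask for '", mask$cell_id, "' produced no boundary contour")
  areas <- vapply(cl, function(cc) polygon_area(cbind(cc$x, cc$y)), 0)
  cc <- cl[[which.max(areas)]]
  cbind(x = cc$x, y = cc$y)
}

#' 2D size- and shape-related parameters of a cell mask
#'
#' Traces the mask boundary as a marching-squares polygon at the 0.5 level
#' and measures area (shoelace), perimeter (polygon length), convex hull
#' area (hull of the boundary vertices), circularity and solidity on that
#' polygon. Polygon-based measurement keeps circularity <= 1 for convex
#' shapes, which naive pixel-edge perimeter counting does not.
#'
#' @param mask A `cell_mask`.
#' @return A list with `area` (um^2), `perimeter` (um), `convex_hull_area`
#'   (um^2), `circularity`, `solidity`.
#' @export
shape_features_2d <- function(mask) {
  if (!inherits(mask, "cell_mask")) stop("mask must be a cell_mask")
  ncomp <- count_components8(mask$grid)
  if (ncomp != 1L)
    stop("mask for '", mask$cell_id, "' has ", ncomp,
         " foreground components; crop to a single cell before measuring")
  poly <- mask_contour(mask)
  feats <- polygon_shape_features(poly)
  if (feats$solidity > 1) feats$solidity <- 1  # guard hull-vs-ring rounding
  feats
}
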