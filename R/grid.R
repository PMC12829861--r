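#' Define a regular planar analysis grid
#'
#' The coarse grid mimics the 10 km "hectad" cells used for British plant
#' recording; a finer subdivision of the same extent (controlled by
#' `fine_factor`) carries elevation and land-cover layers, mimicking the much
#' finer DEM and land-cover rasters. Coordinates are planar metres
#' (northing/easting); cell `(col = 1, row = 1)` sits at the lower-left corner
#' and each cell footprint is the half-open box
#' `[x, x + cell_size) x [y, y + cell_size)`.
#'
#' @param n_cols,n_rows Number of columns / rows (positive integers).
#' @param cell_size Cell edge length in metres (default 10000, a hectad).
#' @param origin_x,origin_y Planar coordinates of the grid's lower-left corner.
#' @param fine_factor Integer >= 1: each coarse cell is subdivided into
#'   `fine_factor^2` fine cells for environmental layers.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_cols, n_rows, cell_size = 10000,
                      origin_x = 0, origin_y = 0, fine_factor = 10) {
  stopifnot(n_cols >= 1, n_rows >= 1, cell_size > 0, fine_factor >= 1,
            n_cols == round(n_cols), n_rows == round(n_rows),
            fine_factor == round(fine_factor))
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 fine_factor = as.integer(fine_factor)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (fine_factor %d)\n",
              x$n_cols, x$n_rows, x$cell_size, x$fine_factor))
  invisible(x)
}

#' Grid extent as (xmin, xmax, ymin, ymax)
#' @param grid A `grid_spec`.
#' @return Named numeric vector of the planar bounding box.
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin_x, xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymin = grid$origin_y, ymax = grid$origin_y + grid$n_rows * grid$cell_size)
}

#' The fine-resolution grid spec underlying a coarse grid
#' @param grid A `grid_spec`.
#' @return A `grid_spec` at `cell_size / fine_factor` resolution covering the
#'   same extent.
#' @export
fine_grid <- function(grid) {
  grid_spec(grid$n_cols * grid$fine_factor, grid$n_rows * grid$fine_factor,
            cell_size = grid$cell_size / grid$fine_factor,
            origin_x = grid$origin_x, origin_y = grid$origin_y,
            fine_factor = 1L)
}

#' Cell-centre coordinates
#' @param grid A `grid_spec`.
#' @return Data frame with `col`, `row`, `x`, `y` (one row per cell, column-major).
#' @export
cell_centers <- function(grid) {
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  data.frame(col = col, row = row,
             x = grid$origin_x + (col - 0.5) * grid$cell_size,
             y = grid$origin_y + (row - 0.5) * grid$cell_size)
}

cell_bounds <- function(grid, col, row) {
  c(xmin = grid$origin_x + (col - 1) * grid$cell_size,
    xmax = grid$origin_x + col * grid$cell_size,
    ymin = grid$origin_y + (row - 1) * grid$cell_size,
    ymax = grid$origin_y + row * grid$cell_size)
}

# Aggregate a fine matrix (n_rows*f x n_cols*f) to the coarse grid by applying
# `fun` over each f x f block. Matrices are indexed [row, col] with row 1 the
# southernmost.
aggregate_fine <- function(mat, f, fun = mean) {
  if (f == 1) return(mat)
  nr <- nrow(mat) / f
  nc <- ncol(mat) / f
  stopifnot(nr == round(nr), nc == round(nc))
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- ((i - 1) * f + 1):(i * f)
    sub <- mat[ri, , drop = FALSE]
    # reshape so each coarse column's block is contiguous
    dim(sub) <- c(f * f, nc)
    out[i, ] <- apply(sub, 2, fun)
  }
  out
}

#' Construct a suitability surface
#'
#' A per-species, per-period surface of habitat-suitability scores in
#' `[0, 1]` (missing values allowed) on a coarse grid.
#'
#' @param species_id Species identifier.
#' @param period `"current"` or `"future"`.
#' @param grid The `grid_spec` of the surface.
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = southernmost row).
#' @return An object of class `suitability_grid`.
#' @export
suitability_grid <- function(species_id, period, grid, values) {
  period <- match.arg(period, c("current", "future"))
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("suitability values must lie in [0, 1]")
  structure(list(species_id = species_id, period = period,
                 grid = grid, values = values),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat(sprintf("<suitability_grid> %s / %s: %d x %d, range [%.3f, %.3f]\n",
              x$species_id, x$period, x$grid$n_rows, x$grid$n_cols,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}
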