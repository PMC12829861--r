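# Minimal planar polygon machinery: the classification rules hinge on the exact
# overlay semantics (a cell counts only if it shares positive area with the
# polygon; boundary contact does not), so the clipping primitive is implemented
# here rather than approximated by cell-centre tests.

#' Create a protected-area polygon
#'
#' @param id Unique identifier string.
#' @param coords Two-column numeric matrix of vertices (x, y), in order, open
#'   ring (first vertex not repeated). Must enclose positive area.
#' @return An object of class `pa_polygon` with fields `id` and `coords`.
#' @export
pa_polygon <- function(id, coords) {
  coords <- as.matrix(coords)
  stopifnot(is.character(id), length(id) == 1L, ncol(coords) == 2,
            nrow(coords) >= 3)
  # drop a closing vertex if present
  if (all(coords[1, ] == coords[nrow(coords), ]))
    coords <- coords[-nrow(coords), , drop = FALSE]
  if (poly_area(coords) <= 0)
    stop("polygon '", id, "' has zero area")
  colnames(coords) <- c("x", "y")
  structure(list(id = id, coords = coords), class = "pa_polygon")
}

#' Create a rectangular protected area
#' @param id Identifier.
#' @param xmin,ymin,xmax,ymax Rectangle bounds in planar metres.
#' @return A `pa_polygon`.
#' @export
pa_rect <- function(id, xmin, ymin, xmax, ymax) {
  pa_polygon(id, cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

#' Shoelace area of a polygon ring
#' @param coords Two-column vertex matrix (open ring).
#' @return Absolute enclosed area.
#' @export
poly_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Polygon centroid (area-weighted)
#' @param coords Two-column vertex matrix (open ring).
#' @return Numeric `c(x, y)`.
#' @export
poly_centroid <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

poly_bbox <- function(coords) {
  c(xmin = min(coords[, 1]), xmax = max(coords[, 1]),
    ymin = min(coords[, 2]), ymax = max(coords[, 2]))
}

# Sutherland-Hodgman clip of a polygon against one half-plane keep(p) >= 0.
clip_halfplane <- function(coords, signed_dist) {
  n <- nrow(coords)
  if (n == 0) return(coords)
  d <- signed_dist(coords)
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di >= 0) { out_x <- c(out_x, coords[i, 1]); out_y <- c(out_y, coords[i, 2]) }
    if ((di < 0) != (dj < 0)) {
      t <- di / (di - dj)
      out_x <- c(out_x, coords[i, 1] + t * (coords[j, 1] - coords[i, 1]))
      out_y <- c(out_y, coords[i, 2] + t * (coords[j, 2] - coords[i, 2]))
    }
  }
  cbind(out_x, out_y)
}

#' Clip a polygon to an axis-aligned rectangle
#' @param coords Two-column vertex matrix (open ring).
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @return Vertex matrix of the intersection (possibly zero rows).
#' @export
clip_poly_rect <- function(coords, xmin, xmax, ymin, ymax) {
  out <- coords
  out <- clip_halfplane(out, function(p) p[, 1] - xmin)
  out <- clip_halfplane(out, function(p) xmax - p[, 1])
  out <- clip_halfplane(out, function(p) p[, 2] - ymin)
  out <- clip_halfplane(out, function(p) ymax - p[, 2])
  out
}

# Area of intersection between a polygon and a rectangle.
poly_rect_area <- function(coords, xmin, xmax, ymin, ymax) {
  cl <- clip_poly_rect(coords, xmin, xmax, ymin, ymax)
  if (nrow(cl) < 3) return(0)
  poly_area(cl)
}

#' Grid cells sharing positive area with a polygon
#'
#' Implements the overlay rule used throughout: a cell belongs to a polygon's
#' zone iff the geometric intersection of the cell footprint and the polygon
#' has positive area. Boundary-touching contact (zero-area) does not count.
#'
#' @param grid A `grid_spec`.
#' @param coords Polygon vertex matrix (or a `pa_polygon`).
#' @return Data frame with columns `col`, `row` (possibly zero rows).
#' @export
cells_intersecting <- function(grid, coords) {
  if (inherits(coords, "pa_polygon")) coords <- coords$coords
  bb <- poly_bbox(coords)
  cs <- grid$cell_size
  c0 <- max(1L, 1L + floor((bb["xmin"] - grid$origin_x) / cs))
  c1 <- min(grid$n_cols, 1L + floor((bb["xmax"] - grid$origin_x) / cs + 1e-12))
  r0 <- max(1L, 1L + floor((bb["ymin"] - grid$origin_y) / cs))
  r1 <- min(grid$n_rows, 1L + floor((bb["ymax"] - grid$origin_y) / cs + 1e-12))
  if (c0 > c1 || r0 > r1)
    return(data.frame(col = integer(0), row = integer(0)))
  tol <- .Machine$double.eps * cs^2 * 16
  cols <- integer(0); rows <- integer(0)
  for (cc in c0:c1) {
    xm <- grid$origin_x + (cc - 1) * cs
    for (rr in r0:r1) {
      ym <- grid$origin_y + (rr - 1) * cs
      if (poly_rect_area(coords, xm, xm + cs, ym, ym + cs) > tol) {
        cols <- c(cols, cc); rows <- c(rows, rr)
      }
    }
  }
  data.frame(col = as.integer(cols), row = as.integer(rows))
}
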