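# Planar polygon primitives used for grid-to-polygon aggregation.
#
# Polygons are simple rings: two-column matrices (x, y), not necessarily
# closed (the closing edge is implied). Cells are axis-aligned rectangles,
# so clipping a ring against a cell (Sutherland-Hodgman) is exact for any
# simple polygon that is convex or for convex clip windows generally.

# Signed area by the shoelace formula; positive for counter-clockwise rings.
ring_area <- function(ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(ring) abs(ring_area(ring))

polygon_centroid <- function(ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  cx <- sum((x[j] + x) * cr) / (6 * a)
  cy <- sum((y[j] + y) * cr) / (6 * a)
  c(x = cx, y = cy)
}

# Clip a ring by the half-plane keep(p) >= 0 along one rectangle edge.
clip_halfplane <- function(ring, inside, intersect) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  out <- matrix(numeric(0), ncol = 2)
  prev <- ring[n, ]
  prev_in <- inside(prev)
  for (k in seq_len(n)) {
    cur <- ring[k, ]
    cur_in <- inside(cur)
    if (cur_in) {
      if (!prev_in) out <- rbind(out, intersect(prev, cur))
      out <- rbind(out, cur)
    } else if (prev_in) {
      out <- rbind(out, intersect(prev, cur))
    }
    prev <- cur
    prev_in <- cur_in
  }
  out
}

# Sutherland-Hodgman clip of a simple ring against rectangle [xmin,xmax]x[ymin,ymax].
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  ring <- clip_halfplane(ring, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  ring <- clip_halfplane(ring, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  ring <- clip_halfplane(ring, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  ring <- clip_halfplane(ring, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  ring
}

# Area of intersection between a ring and one grid cell.
cell_intersection_area <- function(ring, spec, row, col) {
  xmin <- spec$x0 + (col - 1) * spec$dx
  ymin <- spec$y0 + (row - 1) * spec$dy
  clipped <- clip_ring_rect(ring, xmin, xmin + spec$dx, ymin, ymin + spec$dy)
  if (nrow(clipped) < 3) return(0)
  polygon_area(clipped)
}

#' Intersection weights between a polygon and grid cells
#'
#' Computes the area of overlap between a polygon ring and every grid cell it
#' touches, the weights used for area-weighted aggregation of raster values
#' over exposure-unit polygons.
#'
#' @param ring Two-column matrix of polygon vertices (x, y), planar units.
#' @param spec A [grid_spec()].
#' @return A tibble with columns `row`, `col`, `area` (positive overlaps only).
#' @export
polygon_cell_weights <- function(ring, spec) {
  xr <- range(ring[, 1])
  yr <- range(ring[, 2])
  jmin <- max(1L, floor((xr[1] - spec$x0) / spec$dx) + 1L)
  jmax <- min(spec$nx, ceiling((xr[2] - spec$x0) / spec$dx))
  imin <- max(1L, floor((yr[1] - spec$y0) / spec$dy) + 1L)
  imax <- min(spec$ny, ceiling((yr[2] - spec$y0) / spec$dy))
  if (jmin > jmax || imin > imax) {
    return(tibble::tibble(row = integer(), col = integer(), area = numeric()))
  }
  cells <- expand.grid(row = imin:imax, col = jmin:jmax)
  area <- mapply(
    function(i, j) cell_intersection_area(ring, spec, i, j),
    cells$row, cells$col
  )
  keep <- area > 0
  tibble::tibble(
    row = as.integer(cells$row[keep]),
    col = as.integer(cells$col[keep]),
    area = area[keep]
  )
}

# Axis-aligned rectangle ring helper (counter-clockwise).
rect_ring <- function(xmin, xmax, ymin, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Distance between point sets
#'
#' Pairwise distances between two point sets under a pluggable metric:
#' planar Euclidean (km) for synthetic regions, or great-circle haversine for
#' lon/lat coordinates (sphere radius 6371.0088 km, via
#' [geosphere::distHaversine()]).
#'
#' @param p,q Two-column matrices of coordinates (x/y km, or lon/lat degrees).
#' @param metric `"euclidean"` or `"haversine"`.
#' @return A `nrow(p)` x `nrow(q)` matrix of distances in km.
#' @export
distance_matrix <- function(p, q, metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  p <- as.matrix(p)
  q <- as.matrix(q)
  if (metric == "euclidean") {
    dx <- outer(p[, 1], q[, 1], "-")
    dy <- outer(p[, 2], q[, 2], "-")
    sqrt(dx^2 + dy^2)
  } else {
    out <- matrix(0, nrow(p), nrow(q))
    for (k in seq_len(nrow(q))) {
      out[, k] <- geosphere::distHaversine(p, q[k, , drop = FALSE], r = 6371008.8) / 1000
    }
    out
  }
}
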