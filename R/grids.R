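#' Regular grid geometry
#'
#' A `grid_spec` describes a regular raster: the origin (lower-left corner of
#' cell (1,1)), cell sizes, and dimensions. Cell (i, j) spans the half-open
#' rectangle \[x0 + (j-1) dx, x0 + j dx) x \[y0 + (i-1) dy, y0 + i dy).
#' Rows index y (south to north), columns index x (west to east).
#'
#' @param x0,y0 Coordinates of the grid origin (km in the planar frame).
#' @param dx,dy Cell sizes (> 0).
#' @param nx,ny Number of columns and rows.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(x0, y0, dx, dy, nx, ny) {
  stopifnot(dx > 0, dy > 0, nx >= 1, ny >= 1)
  structure(
    list(x0 = x0, y0 = y0, dx = dx, dy = dy, nx = as.integer(nx), ny = as.integer(ny)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %.4g x %.4g, origin (%.4g, %.4g)\n",
    x$ny, x$nx, x$dx, x$dy, x$x0, x$y0
  ))
  invisible(x)
}

# Cell-center coordinate vectors.
cell_centers_x <- function(spec) spec$x0 + (seq_len(spec$nx) - 0.5) * spec$dx
cell_centers_y <- function(spec) spec$y0 + (seq_len(spec$ny) - 0.5) * spec$dy

# Row/col of the cell containing a point (half-open convention, clamped to grid).
cell_index <- function(spec, x, y) {
  j <- pmin(pmax(floor((x - spec$x0) / spec$dx) + 1, 1), spec$nx)
  i <- pmin(pmax(floor((y - spec$y0) / spec$dy) + 1, 1), spec$ny)
  list(row = as.integer(i), col = as.integer(j))
}

#' Daily precipitation grid
#'
#' @param spec A [grid_spec()].
#' @param values Numeric array with dim `c(n_days, ny, nx)`; precipitation in
#'   mm, `NA` for missing. Values must be non-negative where present.
#' @param dates Vector of `Date`s of length `n_days`, strictly increasing.
#' @return An object of class `daily_grid`.
#' @export
daily_grid <- function(spec, values, dates) {
  stopifnot(inherits(spec, "grid_spec"), length(dim(values)) == 3)
  d <- dim(values)
  if (d[2] != spec$ny || d[3] != spec$nx) {
    stop("values dimensions do not match grid spec", call. = FALSE)
  }
  if (d[1] != length(dates)) stop("length(dates) must equal dim(values)[1]", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) stop("precipitation values must be non-negative", call. = FALSE)
  structure(list(spec = spec, values = values, dates = as.Date(dates)), class = "daily_grid")
}

#' Hourly precipitation grid
#'
#' @param spec A [grid_spec()].
#' @param values Numeric array with dim `c(n_days, 24, ny, nx)` (mm).
#' @param dates Vector of `Date`s of length `n_days`.
#' @return An object of class `hourly_grid`.
#' @export
hourly_grid <- function(spec, values, dates) {
  stopifnot(inherits(spec, "grid_spec"), length(dim(values)) == 4)
  d <- dim(values)
  if (d[2] != 24L) stop("hourly grid must have exactly 24 hour layers per day", call. = FALSE)
  if (d[3] != spec$ny || d[4] != spec$nx) {
    stop("values dimensions do not match grid spec", call. = FALSE)
  }
  if (d[1] != length(dates)) stop("length(dates) must equal dim(values)[1]", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) stop("precipitation values must be non-negative", call. = FALSE)
  structure(list(spec = spec, values = values, dates = as.Date(dates)), class = "hourly_grid")
}

#' @export
print.daily_grid <- function(x, ...) {
  cat(sprintf(
    "<daily_grid> %d days x %d x %d cells, %s to %s\n",
    dim(x$values)[1], x$spec$ny, x$spec$nx, min(x$dates), max(x$dates)
  ))
  invisible(x)
}

#' @export
print.hourly_grid <- function(x, ...) {
  cat(sprintf(
    "<hourly_grid> %d days x 24 h x %d x %d cells\n",
    dim(x$values)[1], x$spec$ny, x$spec$nx
  ))
  invisible(x)
}

#' Tidy a daily grid into a long tibble
#'
#' @param x A `daily_grid`.
#' @param ... Unused.
#' @return A tibble with columns `date`, `row`, `col`, `x`, `y`, `prcp_mm`.
#' @export
tidy.daily_grid <- function(x, ...) {
  nd <- dim(x$values)[1]
  cx <- cell_centers_x(x$spec)
  cy <- cell_centers_y(x$spec)
  tibble::tibble(
    date = rep(x$dates, times = x$spec$ny * x$spec$nx),
    row = rep(rep(seq_len(x$spec$ny), each = nd), times = x$spec$nx),
    col = rep(seq_len(x$spec$nx), each = nd * x$spec$ny),
    x = cx[rep(seq_len(x$spec$nx), each = nd * x$spec$ny)],
    y = cy[rep(rep(seq_len(x$spec$ny), each = nd), times = x$spec$nx)],
    prcp_mm = as.vector(x$values)
  )
}
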