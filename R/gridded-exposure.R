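#' Collapse an hourly grid to daily pixel sums
#'
#' Per-pixel sum of the 24 hourly layers of each day. A pixel-day with any
#' missing hour is reported missing.
#'
#' @param hg An [hourly_grid()].
#' @return A [daily_grid()] on the same geometry.
#' @export
hourly_to_daily <- function(hg) {
  if (!inherits(hg, "hourly_grid")) stop("expected an hourly_grid", call. = FALSE)
  d <- dim(hg$values)
  if (d[2] != 24L) stop("malformed hourly grid: expected 24 hour layers", call. = FALSE)
  vals <- apply(hg$values, c(1, 3, 4), function(h) if (anyNA(h)) NA_real_ else sum(h))
  daily_grid(hg$spec, vals, hg$dates)
}

#' Area-weighted polygon average of a daily grid
#'
#' The spatially weighted average of all cell values contained within or
#' intersecting the polygon's border, weighted by intersection area. Cells
#' with missing values are dropped and the weights renormalized; if no
#' intersecting cell has a value, the result is missing with a warning.
#'
#' @param ring Two-column polygon vertex matrix (x, y).
#' @param grid A [daily_grid()].
#' @param day Day index (1-based) or `Date`.
#' @param weights Optional precomputed [polygon_cell_weights()] result.
#' @return Average precipitation (mm) for that polygon-day.
#' @export
area_weighted_average <- function(ring, grid, day, weights = NULL) {
  if (inherits(day, "Date")) day <- match(day, grid$dates)
  if (is.na(day) || day < 1 || day > dim(grid$values)[1]) {
    stop("day outside grid date range", call. = FALSE)
  }
  if (is.null(weights)) weights <- polygon_cell_weights(ring, grid$spec)
  if (nrow(weights) == 0) stop("polygon does not intersect grid extent", call. = FALSE)
  v <- grid$values[cbind(day, weights$row, weights$col)]
  ok <- !is.na(v)
  if (!any(ok)) {
    warning("no non-missing cell intersects polygon; returning NA", call. = FALSE)
    return(NA_real_)
  }
  sum(weights$area[ok] * v[ok]) / sum(weights$area[ok])
}

#' Per-unit daily series from a gridded product
#'
#' Applies the area-weighted average across all days for every exposure unit,
#' producing series with the same schema as the station-assigned series so
#' downstream classification is source-agnostic. Weights are computed once
#' per unit.
#'
#' @param units Exposure-unit tibble with a `geometry` list-column.
#' @param grid A [daily_grid()] (pass an [hourly_grid()] through
#'   [hourly_to_daily()] first).
#' @return Long tibble `unit_id`, `date`, `prcp_mm`.
#' @export
unit_series_from_grid <- function(units, grid) {
  if (inherits(grid, "hourly_grid")) {
    stop("pass hourly grids through hourly_to_daily() first", call. = FALSE)
  }
  nd <- dim(grid$values)[1]
  ncell <- grid$spec$ny * grid$spec$nx
  # flatten day-major: V is ncell x nd
  V <- matrix(aperm(grid$values, c(2, 3, 1)), nrow = ncell, ncol = nd)
  miss <- is.na(V)
  V0 <- ifelse(miss, 0, V)

  series <- purrr::map(seq_len(nrow(units)), function(u) {
    w <- polygon_cell_weights(units$geometry[[u]], grid$spec)
    if (nrow(w) == 0) {
      warning(sprintf("unit %s does not intersect grid extent", units$unit_id[u]), call. = FALSE)
      return(rep(NA_real_, nd))
    }
    flat <- (w$col - 1L) * grid$spec$ny + w$row
    num <- as.vector(crossprod(V0[flat, , drop = FALSE], w$area))
    den <- as.vector(crossprod(1 - miss[flat, , drop = FALSE], w$area))
    out <- num / den
    out[den == 0] <- NA_real_
    out
  })
  tibble::tibble(
    unit_id = rep(units$unit_id, each = nd),
    date = rep(grid$dates, times = nrow(units)),
    prcp_mm = unlist(series)
  )
}

#' Percentile EPE threshold from a grid-derived series
#'
#' Same contract as [local_percentile_threshold()], applied to a unit's
#' grid-derived daily series. By default the quantile is taken over wet days
#' for comparability with station thresholds; `population = "all_days"`
#' reproduces the literal all-days reading of gridded threshold recipes.
#'
#' @inheritParams local_percentile_threshold
#' @return Threshold in mm.
#' @export
grid_percentile_threshold <- function(values, q = 0.99, wet_min_mm = 0,
                                      population = c("wet_days", "all_days"),
                                      type = 7) {
  local_percentile_threshold(values, q, wet_min_mm, match.arg(population), type)
}

#' Per-unit thresholds from grid-derived series
#'
#' @param series Long tibble `unit_id`, `date`, `prcp_mm`.
#' @inheritParams local_percentile_threshold
#' @return Tibble `unit_id`, `threshold_mm` (NA-threshold units dropped with
#'   a warning).
#' @export
unit_thresholds <- function(series, q = 0.99, wet_min_mm = 0,
                            population = c("wet_days", "all_days")) {
  population <- match.arg(population)
  thr_one <- function(v) {
    keep <- !is.na(v)
    if (population == "wet_days") keep <- keep & v > wet_min_mm
    if (!any(keep)) return(NA_real_)
    local_percentile_threshold(v, q, wet_min_mm, population)
  }
  out <- series |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(threshold_mm = thr_one(.data$prcp_mm), .groups = "drop")
  if (anyNA(out$threshold_mm)) {
    warning("dropping unit(s) with no wet days from threshold set", call. = FALSE)
    out <- out[!is.na(out$threshold_mm), ]
  }
  out
}
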