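#' Write exposure units as GeoJSON
#'
#' Polygons as a FeatureCollection with all attribute columns as properties.
#' Coordinates are in the native planar frame (km).
#'
#' @param units Exposure-unit tibble with a `geometry` list-column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(units, path) {
  props <- units[, setdiff(names(units), "geometry"), drop = FALSE]
  features <- purrr::map(seq_len(nrow(units)), function(i) {
    ring <- units$geometry[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE]) # close the ring
    coords <- lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
    list(
      type = "Feature",
      properties = as.list(props[i, , drop = FALSE]),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read exposure units from GeoJSON
#'
#' Inverse of [write_units_geojson()]; expects single-ring polygon features.
#'
#' @param path GeoJSON file path.
#' @return Exposure-unit tibble with a `geometry` list-column.
#' @export
read_units_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- purrr::map(gj$features, function(f) {
    tibble::as_tibble(f$properties)
  })
  units <- dplyr::bind_rows(rows)
  units$geometry <- purrr::map(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    colnames(ring) <- c("x", "y")
    ring[-nrow(ring), , drop = FALSE] # drop the closing vertex
  })
  units
}

#' Write station observations as CSV
#'
#' Schema: `station_id`, `date`, `prcp_mm`, `qc_flag` — the same layout as
#' daily-station extracts from public archives.
#'
#' @param obs Long observation tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Read station observations from CSV
#'
#' @param path CSV file path with `station_id`, `date`, `prcp_mm`, `qc_flag`.
#' @return Long observation tibble.
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$qc_flag <- as.logical(df$qc_flag)
  tibble::as_tibble(df)
}

#' Serialize a grid to long-format CSV
#'
#' Columns `date`(,`hour`),`row`,`col`,`prcp_mm`; the grid geometry travels
#' in a `# grid:` comment header so the file is self-describing.
#'
#' @param grid A [daily_grid()] or [hourly_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  spec <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# grid: x0=%g y0=%g dx=%g dy=%g nx=%d ny=%d",
    spec$x0, spec$y0, spec$dx, spec$dy, spec$nx, spec$ny
  ), con)
  if (inherits(grid, "hourly_grid")) {
    d <- dim(grid$values)
    df <- data.frame(
      date = rep(grid$dates, times = 24 * d[3] * d[4]),
      hour = rep(rep(seq_len(24), each = d[1]), times = d[3] * d[4]),
      row = rep(rep(seq_len(d[3]), each = d[1] * 24), times = d[4]),
      col = rep(seq_len(d[4]), each = d[1] * 24 * d[3]),
      prcp_mm = as.vector(grid$values)
    )
  } else {
    d <- dim(grid$values)
    df <- data.frame(
      date = rep(grid$dates, times = d[2] * d[3]),
      row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      col = rep(seq_len(d[3]), each = d[1] * d[2]),
      prcp_mm = as.vector(grid$values)
    )
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a region configuration from YAML
#'
#' The file holds a flat mapping of [region_config()] fields; unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return A validated `region_config`.
#' @export
read_region_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(region_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if ("start_date" %in% names(vals)) vals$start_date <- as.Date(vals$start_date)
  do.call(region_config, vals)
}
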