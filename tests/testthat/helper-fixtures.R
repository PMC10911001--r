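# Shared fixtures and independent oracles.

# Small region config without the short-record warning noise.
tiny_config <- function(...) {
  suppressWarnings(region_config(...))
}

# Minimal exposure-unit tibble: an n x n tessellation of square tracts of
# side `tract_km`, with just the columns a test needs.
toy_units <- function(n_side = 2, tract_km = 10) {
  idx <- expand.grid(row = seq_len(n_side), col = seq_len(n_side))
  tibble::tibble(
    unit_id = sprintf("U%02d", seq_len(n_side^2)),
    geometry = purrr::map2(idx$col, idx$row, function(j, i) {
      epeagree:::rect_ring((j - 1) * tract_km, j * tract_km, (i - 1) * tract_km, i * tract_km)
    }),
    centroid_x = (idx$col - 0.5) * tract_km,
    centroid_y = (idx$row - 0.5) * tract_km
  )
}

# Long observation tibble from a stations-by-days value matrix (NA = offline).
toy_obs <- function(values, dates, station_ids = sprintf("S%02d", seq_len(nrow(values))),
                    qc = NULL) {
  if (is.null(qc)) qc <- matrix(FALSE, nrow(values), ncol(values))
  tibble::tibble(
    station_id = rep(station_ids, times = ncol(values)),
    date = rep(dates, each = nrow(values)),
    prcp_mm = as.vector(values),
    qc_flag = as.vector(qc)
  )
}

# Independent kappa oracle: straight from two paired vectors, no contingency
# shortcut shared with the implementation.
kappa_oracle <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  p_o <- mean(a == b)
  p_e <- mean(a == 1) * mean(b == 1) + mean(a == 0) * mean(b == 0)
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Exhaustive nearest-operating-station search, one unit-day at a time, with
# explicit lexicographic tie-breaking via order().
nearest_oracle <- function(units, stations, value_matrix, dates) {
  nu <- nrow(units)
  nd <- length(dates)
  uid <- character(nu * nd)
  dt <- rep(as.Date(NA), nu * nd)
  val <- numeric(nu * nd)
  sid <- character(nu * nd)
  k <- 0L
  for (d in seq_along(dates)) {
    avail <- which(!is.na(value_matrix[, d]))
    for (u in seq_len(nu)) {
      k <- k + 1L
      uid[k] <- units$unit_id[u]
      dt[k] <- dates[d]
      if (length(avail) == 0) {
        val[k] <- NA_real_
        sid[k] <- NA_character_
        next
      }
      dist <- sqrt((stations$x - units$centroid_x[u])^2 +
        (stations$y - units$centroid_y[u])^2)
      ord <- avail[order(dist[avail], stations$station_id[avail])]
      pick <- ord[1]
      val[k] <- value_matrix[pick, d]
      sid[k] <- stations$station_id[pick]
    }
  }
  data.frame(unit_id = uid, date = dt, prcp_mm = val, station_id = sid)
}
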