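#' Remove quality-flagged observations
#'
#' Observations carrying a QC flag are set to missing; clean days are left
#' unchanged. The number of removed station-days is reported as a message.
#'
#' @param obs Long observation tibble with at least `prcp_mm` and `qc_flag`.
#' @param quiet Suppress the removal-count message.
#' @return The tibble with flagged values replaced by `NA` (flags retained).
#' @export
filter_qc <- function(obs, quiet = FALSE) {
  removed <- sum(obs$qc_flag & !is.na(obs$prcp_mm), na.rm = TRUE)
  obs$prcp_mm[which(obs$qc_flag)] <- NA_real_
  if (!quiet && removed > 0) {
    message(sprintf("filter_qc: removed %d flagged station-day value(s)", removed))
  }
  obs
}

#' Record completeness over a period
#'
#' Fraction of days in the period with a clean, non-missing observation.
#' QC-flagged days count as absent (the completeness screen is applied after
#' flag removal).
#'
#' @param obs Long observation tibble (`station_id`, `date`, `prcp_mm`,
#'   `qc_flag`).
#' @param period Vector of `Date`s defining the evaluation period.
#' @return Tibble with `station_id` and `completeness` in \[0, 1\].
#' @export
completeness <- function(obs, period) {
  if (length(period) == 0) stop("period must be non-empty", call. = FALSE)
  period <- as.Date(period)
  obs <- filter_qc(obs[obs$date %in% period, , drop = FALSE], quiet = TRUE)
  obs |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      completeness = sum(!is.na(.data$prcp_mm)) / length(period),
      .groups = "drop"
    )
}

#' Subset stations meeting a completeness screen
#'
#' Stations whose clean-observation completeness over the period is at or
#' above `min_completeness` (default 99%), the strict inclusion criterion
#' used to anchor local percentile thresholds.
#'
#' @param stations Station tibble (`station_id`, coordinates, ...).
#' @param obs Long observation tibble.
#' @param period Vector of `Date`s.
#' @param min_completeness Inclusion threshold (default 0.99, inclusive).
#' @return The subset of `stations`; warns when empty.
#' @export
select_threshold_stations <- function(stations, obs, period, min_completeness = 0.99) {
  comp <- completeness(obs, period)
  keep <- comp$station_id[comp$completeness >= min_completeness]
  out <- stations[stations$station_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no station meets the completeness screen", call. = FALSE)
  }
  out
}

#' Local percentile EPE threshold
#'
#' The q-quantile of the wet-day precipitation distribution (days with value
#' strictly above `wet_min_mm`), using the linear-interpolation quantile
#' convention (R type 7). With `population = "all_days"` the quantile is
#' taken over all non-missing days instead, the literal reading of the
#' gridded-threshold recipe.
#'
#' @param values Numeric vector of daily precipitation (mm), `NA` allowed.
#' @param q Quantile level (default 0.99).
#' @param wet_min_mm Wet-day cutoff (default 0: strictly positive is wet).
#' @param population `"wet_days"` (default) or `"all_days"`.
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return Threshold in mm.
#' @export
local_percentile_threshold <- function(values, q = 0.99, wet_min_mm = 0,
                                       population = c("wet_days", "all_days"),
                                       type = 7) {
  population <- match.arg(population)
  v <- values[!is.na(values)]
  if (population == "wet_days") v <- v[v > wet_min_mm]
  if (length(v) == 0) {
    stop("threshold undefined: no wet days in series", call. = FALSE)
  }
  unname(stats::quantile(v, probs = q, type = type))
}

#' Per-station percentile thresholds
#'
#' Applies [local_percentile_threshold()] to each station's clean series.
#' Stations whose series has no wet day are dropped with a warning.
#'
#' @param obs Long observation tibble.
#' @inheritParams local_percentile_threshold
#' @return Tibble `station_id`, `threshold_mm`.
#' @export
station_thresholds <- function(obs, q = 0.99, wet_min_mm = 0,
                               population = c("wet_days", "all_days")) {
  population <- match.arg(population)
  obs <- filter_qc(obs, quiet = TRUE)
  thr_one <- function(v) {
    keep <- !is.na(v)
    if (population == "wet_days") keep <- keep & v > wet_min_mm
    if (!any(keep)) return(NA_real_)
    local_percentile_threshold(v, q, wet_min_mm, population)
  }
  out <- obs |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(threshold_mm = thr_one(.data$prcp_mm), .groups = "drop")
  if (any(is.na(out$threshold_mm))) {
    warning("dropping station(s) with no wet days from threshold set", call. = FALSE)
    out <- out[!is.na(out$threshold_mm), ]
  }
  out[, c("station_id", "threshold_mm")]
}

# Sort stations lexicographically so which.min/max.col tie-breaking by first
# index implements the documented lexicographic-station_id tie rule.
sort_stations <- function(stations) stations[order(stations$station_id), , drop = FALSE]

unit_station_distances <- function(units, stations, metric = "euclidean") {
  distance_matrix(
    cbind(units$centroid_x, units$centroid_y),
    cbind(stations$x, stations$y),
    metric = metric
  )
}

#' Assign each unit the threshold of its nearest included station
#'
#' Static nearest-neighbour assignment from unit centroids to the
#' completeness-screened station set; equidistant ties go to the
#' lexicographically lowest `station_id`.
#'
#' @param units Exposure-unit tibble (`unit_id`, `centroid_x`, `centroid_y`).
#' @param threshold_stations Screened station tibble.
#' @param thresholds Tibble `station_id`, `threshold_mm` from
#'   [station_thresholds()].
#' @param metric Distance metric for [distance_matrix()].
#' @return Tibble `unit_id`, `station_id`, `distance_km`, `threshold_mm`.
#' @export
assign_station_thresholds <- function(units, threshold_stations, thresholds,
                                      metric = "euclidean") {
  st <- sort_stations(threshold_stations)
  st <- st[st$station_id %in% thresholds$station_id, , drop = FALSE]
  if (nrow(st) == 0) stop("no threshold stations available", call. = FALSE)
  D <- unit_station_distances(units, st, metric)
  nearest <- max.col(-D, ties.method = "first")
  thr <- thresholds$threshold_mm[match(st$station_id[nearest], thresholds$station_id)]
  tibble::tibble(
    unit_id = units$unit_id,
    station_id = st$station_id[nearest],
    distance_km = D[cbind(seq_len(nrow(units)), nearest)],
    threshold_mm = thr
  )
}

#' Assign daily values from the nearest operating station
#'
#' For each unit and day, takes the value of the nearest station that has a
#' clean, non-missing observation that day; the assigning station may change
#' from day to day as stations drop in and out. Days with no reporting
#' station anywhere yield missing unit-days.
#'
#' @param units Exposure-unit tibble.
#' @param stations Station tibble (all stations, not only screened ones).
#' @param obs Long observation tibble.
#' @param metric Distance metric.
#' @return Long tibble `unit_id`, `date`, `prcp_mm`, `station_id`,
#'   `distance_km`.
#' @export
assign_daily_values <- function(units, stations, obs, metric = "euclidean") {
  st <- sort_stations(stations)
  obs <- filter_qc(obs, quiet = TRUE)
  wide <- tidyr::pivot_wider(obs,
    id_cols = "date", names_from = "station_id", values_from = "prcp_mm"
  )
  wide <- wide[order(wide$date), ]
  missing_cols <- setdiff(st$station_id, names(wide))
  for (m in missing_cols) wide[[m]] <- NA_real_
  vmat <- as.matrix(wide[, st$station_id, drop = FALSE])
  D <- unit_station_distances(units, st, metric)
  nd <- nrow(wide)
  nu <- nrow(units)

  value <- matrix(NA_real_, nu, nd)
  src <- matrix(NA_character_, nu, nd)
  dist <- matrix(NA_real_, nu, nd)
  for (d in seq_len(nd)) {
    avail <- !is.na(vmat[d, ])
    if (!any(avail)) next
    Dm <- D
    Dm[, !avail] <- Inf
    nearest <- max.col(-Dm, ties.method = "first")
    value[, d] <- vmat[d, nearest]
    src[, d] <- st$station_id[nearest]
    dist[, d] <- D[cbind(seq_len(nu), nearest)]
  }
  tibble::tibble(
    unit_id = rep(units$unit_id, times = nd),
    date = rep(wide$date, each = nu),
    prcp_mm = as.vector(value),
    station_id = as.vector(src),
    distance_km = as.vector(dist)
  )
}

#' Distance stratum labels
#'
#' Bins a mean daily distance (km) into the station-proximity strata
#' \[0, 7), \[7, 30\], (30, Inf): `"0-7 km"`, `"7-30 km"`, `">30 km"`.
#'
#' @param d Numeric distances in km.
#' @return Character vector of stratum labels.
#' @export
distance_stratum <- function(d) {
  dplyr::case_when(
    is.na(d) ~ NA_character_,
    d < 7 ~ "0-7 km",
    d <= 30 ~ "7-30 km",
    TRUE ~ ">30 km"
  )
}

#' Mean daily distance to the nearest operating station
#'
#' For each unit, the distance from its centroid to the nearest station with
#' a clean observation is computed per day; the mean of these daily distances
#' over the period defines the unit's proximity profile and stratum. Days
#' with no reporting station contribute nothing; a unit with no contributing
#' day at all raises an error.
#'
#' @param units Exposure-unit tibble.
#' @param stations Station tibble.
#' @param obs Long observation tibble.
#' @param period Optional vector of `Date`s to restrict to.
#' @param metric Distance metric.
#' @return Tibble `unit_id`, `mean_daily_distance_km`, `stratum`.
#' @export
distance_profile <- function(units, stations, obs, period = NULL,
                             metric = "euclidean") {
  if (!is.null(period)) {
    if (length(period) == 0) stop("period must be non-empty", call. = FALSE)
    obs <- obs[obs$date %in% as.Date(period), , drop = FALSE]
  }
  assigned <- assign_daily_values(units, stations, obs, metric)
  ok <- assigned[!is.na(assigned$distance_km), , drop = FALSE]
  if (nrow(ok) == 0) stop("no day with an operating station in period", call. = FALSE)
  ok |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      mean_daily_distance_km = mean(.data$distance_km),
      .groups = "drop"
    ) |>
    dplyr::mutate(stratum = distance_stratum(.data$mean_daily_distance_km)) |>
    dplyr::arrange(match(.data$unit_id, units$unit_id))
}
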