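dates10 <- as.Date("2015-01-01") + 0:9

test_that("filter_qc blanks flagged days and leaves clean days alone", {
  obs <- toy_obs(matrix(1:10, 1), dates10, "S01",
    qc = matrix(c(rep(TRUE, 3), rep(FALSE, 7)), 1)
  )
  out <- filter_qc(obs, quiet = TRUE)
  expect_equal(sum(is.na(out$prcp_mm)), 3)
  expect_equal(out$prcp_mm[!out$qc_flag], 4:10)

  clean <- toy_obs(matrix(as.numeric(1:10), 1), dates10, "S01")
  expect_identical(filter_qc(clean, quiet = TRUE), clean)

  allflag <- toy_obs(matrix(1:10, 1), dates10, "S01", qc = matrix(TRUE, 1, 10))
  expect_true(all(is.na(filter_qc(allflag, quiet = TRUE)$prcp_mm)))
})

test_that("completeness counts clean days over the period", {
  dates <- as.Date("2015-01-01") + 0:99
  v <- matrix(runif(100), 1)
  expect_equal(completeness(toy_obs(v, dates, "S01"), dates)$completeness, 1)

  v2 <- v
  v2[1, 100] <- NA
  expect_equal(completeness(toy_obs(v2, dates, "S01"), dates)$completeness, 0.99)

  # flagged days count as absent
  qc <- matrix(FALSE, 1, 100)
  qc[1, 1:2] <- TRUE
  expect_equal(completeness(toy_obs(v, dates, "S01", qc), dates)$completeness, 0.98)

  expect_error(completeness(toy_obs(v, dates, "S01"), as.Date(character())), "non-empty")
})

test_that("completeness never increases after QC filtering", {
  set.seed(21)
  dates <- as.Date("2015-01-01") + 0:199
  for (rep in 1:10) {
    v <- matrix(ifelse(runif(200) < 0.1, NA, rgamma(200, 1)), 1)
    qc <- matrix(runif(200) < 0.15, 1)
    obs <- toy_obs(v, dates, "S01", qc)
    pre <- sum(!is.na(obs$prcp_mm)) / 200
    post <- completeness(obs, dates)$completeness
    expect_lte(post, pre)
  }
})

test_that("completeness screen is inclusive at the threshold", {
  dates <- as.Date("2015-01-01") + 0:999
  v <- matrix(runif(3000), 3)
  v[1, 1:10] <- NA # 0.990 -> kept
  v[2, 1:11] <- NA # 0.989 -> excluded
  stations <- tibble::tibble(station_id = c("S01", "S02", "S03"), x = 1:3, y = 1:3)
  kept <- select_threshold_stations(stations, toy_obs(v, dates), dates)
  expect_setequal(kept$station_id, c("S01", "S03"))

  v[3, 1:30] <- NA
  v[1, 11:30] <- NA
  expect_warning(
    empty <- select_threshold_stations(stations, toy_obs(v, dates), dates,
      min_completeness = 0.999
    ),
    "no station"
  )
  expect_equal(nrow(empty), 0)
})

test_that("local percentile threshold follows the linear-interpolation convention", {
  expect_equal(local_percentile_threshold(1:100, 0.99), 99.01)
  expect_equal(local_percentile_threshold(rep(5, 20), 0.99), 5)
  expect_error(local_percentile_threshold(rep(0, 30)), "no wet days")
  # wet-day restriction: zeros are excluded before the quantile
  expect_equal(local_percentile_threshold(c(rep(0, 50), 1:100), 0.99), 99.01)
  # configurable wet minimum
  expect_equal(local_percentile_threshold(c(0.05, 1:10), 0.5, wet_min_mm = 0.1), 5.5)
  # all-days population includes dry days
  expect_equal(
    local_percentile_threshold(c(0, 0, 4), 0.5, population = "all_days"),
    unname(quantile(c(0, 0, 4), 0.5))
  )
})

test_that("exceedances of a station's own 99th-percentile threshold are rare", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(400:3000, 1)
    v <- ifelse(runif(n) < 0.3, rgamma(n, 0.8, scale = 9), 0)
    if (!any(v > 0)) next
    thr <- local_percentile_threshold(v, 0.99)
    n_wet <- sum(v > 0)
    expect_lte(sum(v > thr), ceiling(0.01 * n_wet))
  }
})

test_that("threshold assignment is nearest-station with lexicographic ties", {
  units <- toy_units(2, 10)
  stations <- tibble::tibble(
    station_id = c("S02", "S01"), # deliberately unsorted
    x = c(5, 15), y = c(5, 5)
  )
  thr <- tibble::tibble(station_id = c("S01", "S02"), threshold_mm = c(10, 20))

  # single included station: all units share its threshold
  one <- assign_station_thresholds(units, stations[1, ], thr)
  expect_true(all(one$threshold_mm == 20))

  res <- assign_station_thresholds(units, stations, thr)
  expect_equal(res$station_id[res$unit_id == "U01"], "S02") # centroid (5,5), exact hit
  expect_equal(res$station_id[res$unit_id == "U03"], "S01") # centroid (15,5), exact hit

  # equidistant tie: units U03 (5,15) and U04 (15,15) are 10 and 10*sqrt(2)
  # from the two stations; build a true tie instead
  tie_units <- tibble::tibble(
    unit_id = "X", geometry = list(epeagree:::rect_ring(9, 11, 0, 2)),
    centroid_x = 10, centroid_y = 5
  )
  tie <- assign_station_thresholds(tie_units, stations, thr)
  expect_equal(tie$station_id, "S01")

  expect_error(assign_station_thresholds(units, stations[0, ], thr), "no threshold stations")
})

test_that("daily assignment falls back to the nearest operating station", {
  units <- toy_units(1, 10) # one unit, centroid (5,5)
  dates <- as.Date("2015-06-01") + 0:2
  stations <- tibble::tibble(station_id = c("S01", "S02"), x = c(6, 20), y = c(5, 5))
  v <- matrix(c(
    1, NA, 3, # S01 offline day 2
    10, 20, 30
  ), 2, 3, byrow = TRUE)
  out <- assign_daily_values(units, stations, toy_obs(v, dates))
  expect_equal(out$prcp_mm, c(1, 20, 3))
  expect_equal(out$station_id, c("S01", "S02", "S01"))

  # single-station network: unit series equals station series
  single <- assign_daily_values(units, stations[1, ], toy_obs(v[1, , drop = FALSE], dates, "S01"))
  expect_equal(single$prcp_mm, c(1, NA, 3))

  # no station reporting on a day: unit-day missing
  v2 <- v
  v2[, 2] <- NA
  none <- assign_daily_values(units, stations, toy_obs(v2, dates))
  expect_true(is.na(none$prcp_mm[none$date == dates[2]]))
})

test_that("daily assignment matches the exhaustive nearest-search oracle", {
  set.seed(17)
  units <- toy_units(3, 8)
  ns <- 10
  nd <- 30
  dates <- as.Date("2015-01-01") + seq_len(nd) - 1
  stations <- tibble::tibble(
    station_id = sprintf("S%02d", 1:ns),
    x = runif(ns, 0, 24), y = runif(ns, 0, 24)
  )
  # duplicate a location to force distance ties
  stations$x[2] <- stations$x[1]
  stations$y[2] <- stations$y[1]
  v <- matrix(rgamma(ns * nd, 1), ns, nd)
  v[matrix(runif(ns * nd) < 0.3, ns, nd)] <- NA
  got <- assign_daily_values(units, stations, toy_obs(v, dates))
  want <- nearest_oracle(units, stations, v, dates)
  key <- function(df) df[order(df$unit_id, df$date), c("unit_id", "prcp_mm", "station_id")]
  expect_equal(
    unname(as.data.frame(key(got))),
    unname(key(want)),
    ignore_attr = TRUE
  )
})

test_that("distance profiles average daily nearest distances and bin correctly", {
  expect_equal(distance_stratum(c(6.999, 7, 30, 30.001)),
    c("0-7 km", "7-30 km", "7-30 km", ">30 km"))

  units <- toy_units(1, 10)
  dates <- as.Date("2015-01-01") + 0:1
  stations <- tibble::tibble(station_id = c("S01", "S02"), x = c(5, 5), y = c(8, 25))
  # day 1 both operate (nearest 3 km), day 2 only the far one (20 km)
  v <- matrix(c(1, NA, 2, 3), 2, 2, byrow = TRUE)
  prof <- distance_profile(units, stations, toy_obs(v, dates))
  expect_equal(prof$mean_daily_distance_km, (3 + 20) / 2)
  expect_equal(prof$stratum, "7-30 km")

  # static network: mean equals the static nearest distance
  v2 <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  prof2 <- distance_profile(units, stations, toy_obs(v2, dates))
  expect_equal(prof2$mean_daily_distance_km, 3)

  expect_error(
    distance_profile(units, stations, toy_obs(matrix(NA_real_, 2, 2), dates)),
    "no day"
  )
})

test_that("adding a station never increases any unit's mean distance", {
  set.seed(23)
  units <- toy_units(3, 10)
  dates <- as.Date("2015-01-01") + 0:19
  ns <- 6
  stations <- tibble::tibble(
    station_id = sprintf("S%02d", 1:ns),
    x = runif(ns, 0, 30), y = runif(ns, 0, 30)
  )
  v <- matrix(rgamma(ns * 20, 1), ns, 20)
  before <- distance_profile(units, stations[1:5, ], toy_obs(v[1:5, ], dates,
    station_ids = stations$station_id[1:5]
  ))
  after <- distance_profile(units, stations, toy_obs(v, dates))
  expect_true(all(after$mean_daily_distance_km <= before$mean_daily_distance_km + 1e-12))
})
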