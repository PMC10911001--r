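#' Configuration for a synthetic study region
#'
#' Defines the study conditions for a self-contained synthetic region: a
#' square domain tessellated into square tracts (the exposure units), a fine
#' "truth" precipitation grid, a demographically biased station network, and
#' two derived gridded products (a station-interpolated fine product and a
#' noised, hourly-disaggregated coarse product).
#'
#' @param region_size_km Side of the square region (km).
#' @param n_tracts_side Tracts per side; the region holds `n_tracts_side^2`
#'   square exposure units. Must be >= 2.
#' @param n_days Number of simulated days. Below 365 the local 99th-percentile
#'   thresholds rest on few wet days, so a warning is issued.
#' @param n_stations Number of stations to place (>= 1).
#' @param siting_bias Strength (>= 0) of station-density reduction in
#'   high-vulnerability tracts: placement intensity is proportional to
#'   `exp(-siting_bias * SVI)` of the containing tract. 0 = unbiased siting.
#' @param wet_prob Marginal probability a cell-day is wet, in (0, 1).
#' @param spatial_range_km Correlation length (km) of the exponential-
#'   covariance Gaussian fields driving occurrence, amounts and demographics.
#' @param gamma_shape,gamma_scale Shape and scale (mm) of the gamma wet-day
#'   amount distribution.
#' @param obs_noise_sd Gauge observation noise SD (mm, additive, >= 0).
#' @param missing_rate Long-run fraction of station-days lost to outages.
#' @param qc_flag_rate Fraction of observed station-days carrying a quality
#'   flag (flagged values are removed by [filter_qc()]).
#' @param seed Integer seed; all outputs are deterministic given the config.
#' @param fine_cells_per_tract Fine-grid cells per tract side (default 4).
#' @param coarse_factor Fine cells per coarse cell side (default 4). The fine
#'   grid dimension must be divisible by this.
#' @param assim_noise_sd Lognormal sigma of the multiplicative noise applied
#'   to the coarse assimilation product (log scale; mean-one noise).
#' @param outage_mean_len Mean length (days) of geometric station outage blocks.
#' @param start_date First simulated day.
#' @return A validated list of class `region_config`.
#' @seealso [generate_region()]
#' @export
region_config <- function(region_size_km = 120,
                          n_tracts_side = 8,
                          n_days = 730,
                          n_stations = 15,
                          siting_bias = 2,
                          wet_prob = 0.3,
                          spatial_range_km = 30,
                          gamma_shape = 0.9,
                          gamma_scale = 8,
                          obs_noise_sd = 0.5,
                          missing_rate = 0.05,
                          qc_flag_rate = 0.002,
                          seed = 1,
                          fine_cells_per_tract = 4,
                          coarse_factor = 4,
                          assim_noise_sd = 0.3,
                          outage_mean_len = 10,
                          start_date = as.Date("2011-01-01")) {
  cfg <- list(
    region_size_km = region_size_km, n_tracts_side = as.integer(n_tracts_side),
    n_days = as.integer(n_days), n_stations = as.integer(n_stations),
    siting_bias = siting_bias, wet_prob = wet_prob,
    spatial_range_km = spatial_range_km,
    gamma_shape = gamma_shape, gamma_scale = gamma_scale,
    obs_noise_sd = obs_noise_sd, missing_rate = missing_rate,
    qc_flag_rate = qc_flag_rate, seed = as.integer(seed),
    fine_cells_per_tract = as.integer(fine_cells_per_tract),
    coarse_factor = as.integer(coarse_factor),
    assim_noise_sd = assim_noise_sd, outage_mean_len = outage_mean_len,
    start_date = as.Date(start_date)
  )
  bad <- function(field, why) {
    stop(sprintf("invalid region_config: `%s` %s", field, why), call. = FALSE)
  }
  if (!is.finite(cfg$region_size_km) || cfg$region_size_km <= 0) bad("region_size_km", "must be positive")
  if (is.na(cfg$n_tracts_side) || cfg$n_tracts_side < 2) bad("n_tracts_side", "must be >= 2")
  if (is.na(cfg$n_days) || cfg$n_days < 1) bad("n_days", "must be >= 1")
  if (is.na(cfg$n_stations) || cfg$n_stations < 1) bad("n_stations", "must be >= 1")
  if (!is.finite(cfg$siting_bias) || cfg$siting_bias < 0) bad("siting_bias", "must be >= 0")
  for (p in c("wet_prob", "missing_rate", "qc_flag_rate")) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) bad(p, "must be a probability in [0, 1]")
  }
  if (cfg$wet_prob >= 1) bad("wet_prob", "must be < 1")
  if (!is.finite(cfg$spatial_range_km) || cfg$spatial_range_km <= 0) bad("spatial_range_km", "must be positive")
  if (!is.finite(cfg$gamma_shape) || cfg$gamma_shape <= 0) bad("gamma_shape", "must be positive")
  if (!is.finite(cfg$gamma_scale) || cfg$gamma_scale <= 0) bad("gamma_scale", "must be positive")
  if (!is.finite(cfg$obs_noise_sd) || cfg$obs_noise_sd < 0) bad("obs_noise_sd", "must be >= 0")
  if (is.na(cfg$fine_cells_per_tract) || cfg$fine_cells_per_tract < 1) bad("fine_cells_per_tract", "must be >= 1")
  nfine <- cfg$n_tracts_side * cfg$fine_cells_per_tract
  if (is.na(cfg$coarse_factor) || cfg$coarse_factor < 1 || nfine %% cfg$coarse_factor != 0) {
    bad("coarse_factor", "must divide the fine grid dimension")
  }
  if (!is.finite(cfg$assim_noise_sd) || cfg$assim_noise_sd < 0) bad("assim_noise_sd", "must be >= 0")
  if (!is.finite(cfg$outage_mean_len) || cfg$outage_mean_len < 1) bad("outage_mean_len", "must be >= 1")
  if (cfg$n_days < 365) {
    warning("n_days < 365: percentile EPE thresholds will be unstable", call. = FALSE)
  }
  structure(cfg, class = "region_config")
}

fine_spec <- function(config) {
  n <- config$n_tracts_side * config$fine_cells_per_tract
  d <- config$region_size_km / n
  grid_spec(0, 0, d, d, n, n)
}

coarse_spec <- function(config) {
  nf <- config$n_tracts_side * config$fine_cells_per_tract
  n <- nf %/% config$coarse_factor
  d <- config$region_size_km / n
  grid_spec(0, 0, d, d, n, n)
}

region_dates <- function(config) config$start_date + seq_len(config$n_days) - 1L

#' Generate tract polygons with demographic and vulnerability attributes
#'
#' Tracts are square tiles. Racial/ethnic composition is drawn from a
#' Dirichlet whose concentrations vary smoothly over space (spatially
#' autocorrelated logits); poverty follows a smooth logit; the social
#' vulnerability index (SVI) is the percentile rank of a poverty + minority
#' composite, so SVI has a uniform marginal over tracts. A shared smooth
#' "remoteness" field raises Native American share, poverty and elevation
#' together, emulating the empirical pattern that majority-Native tracts tend
#' to be rugged, sparse and high-vulnerability. Urbanicity is assigned by
#' population-density terciles.
#'
#' @param config A [region_config()].
#' @return A list with `units` (tibble of exposure units) and `elevation`
#'   (static raster: list of `spec` and matrix `values`, km).
#' @keywords internal
generate_units <- function(config) {
  spec <- fine_spec(config)
  n_side <- config$n_tracts_side
  n_units <- n_side^2
  tract_km <- config$region_size_km / n_side

  with_seed(child_seed(config$seed, 1), {
    spectrum <- grf_spectrum(spec, config$spatial_range_km)
    f <- grf_simulate(spectrum, 8) # base, black, asian, hisp, dens, pov, elev, remote
    idx <- expand.grid(row = seq_len(n_side), col = seq_len(n_side))
    cx <- (idx$col - 0.5) * tract_km
    cy <- (idx$row - 0.5) * tract_km
    at <- function(k) grf_at_points(f[k, , ], spec, cx, cy)

    remote <- at(8)
    alpha <- cbind(
      white    = exp(1.6 + 0.6 * at(1)),
      black    = exp(-0.3 + 0.9 * at(2)),
      native   = exp(-1.6 + 2.0 * remote),
      asian    = exp(-1.3 + 0.9 * at(3)),
      hispanic = exp(-0.5 + 0.9 * at(4)),
      other    = exp(-2.3 + 0 * remote)
    )
    g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1), nrow = n_units)
    shares <- g / rowSums(g)
    colnames(shares) <- colnames(alpha)

    pct_poverty <- 100 * stats::plogis(-1.8 + 0.9 * at(6) + 0.9 * remote)
    pct_minority <- 100 * (1 - shares[, "white"])
    composite <- as.numeric(scale(pct_poverty)) + as.numeric(scale(pct_minority))
    svi <- (rank(composite, ties.method = "first") - 0.5) / n_units

    pop_density <- exp(-1.2 + 1.3 * at(5) - 0.6 * remote) # 1,000 persons / km^2
    terc <- stats::quantile(pop_density, c(1 / 3, 2 / 3), type = 7)
    urbanicity <- cut(pop_density, c(-Inf, terc, Inf),
      labels = c("rural", "urban cluster", "urban")
    )

    elev_values <- pmax(0, 0.5 + 0.3 * f[7, , ] + 0.25 * f[8, , ])
    elevation <- list(spec = spec, values = elev_values)

    geometry <- purrr::map2(idx$col, idx$row, function(j, i) {
      rect_ring((j - 1) * tract_km, j * tract_km, (i - 1) * tract_km, i * tract_km)
    })
    units <- tibble::tibble(
      unit_id = sprintf("T%03d", seq_len(n_units)),
      geometry = geometry,
      centroid_x = cx,
      centroid_y = cy,
      pct_minority = pct_minority,
      pct_black = 100 * shares[, "black"],
      pct_native_american = 100 * shares[, "native"],
      pct_asian = 100 * shares[, "asian"],
      pct_hispanic = 100 * shares[, "hispanic"],
      pct_poverty = pct_poverty,
      svi = svi,
      urbanicity = as.character(urbanicity),
      pop_density = pop_density
    )
    units$prominence_km <- vapply(
      units$geometry,
      function(ring) prominence_from_elevation(ring, elevation),
      numeric(1)
    )
    list(units = units, elevation = elevation)
  })
}

#' Simulate the fine-grid "truth" precipitation field
#'
#' Daily wet/dry occurrence is a thresholded spatially correlated Gaussian
#' field with marginal wet probability `wet_prob`; wet-day amounts are gamma
#' distributed, driven by a second correlated field so that extreme days are
#' spatially coherent. Dry cells are exactly zero.
#'
#' @param config A [region_config()].
#' @return A [daily_grid()] on the fine grid (mm).
#' @export
generate_truth_field <- function(config) {
  stopifnot(inherits(config, "region_config"))
  spec <- fine_spec(config)
  with_seed(child_seed(config$seed, 2), {
    nd <- config$n_days
    vals <- array(0, dim = c(nd, spec$ny, spec$nx))
    if (config$wet_prob > 0) {
      spectrum <- grf_spectrum(spec, config$spatial_range_km)
      zcrit <- stats::qnorm(1 - config$wet_prob)
      for (d in seq_len(nd)) {
        occ <- grf_simulate(spectrum, 1)[1, , ]
        amt <- grf_simulate(spectrum, 1)[1, , ]
        wet <- occ > zcrit
        x <- stats::qgamma(stats::pnorm(amt), shape = config$gamma_shape, scale = config$gamma_scale)
        vals[d, , ] <- ifelse(wet, x, 0)
      }
    }
    daily_grid(spec, vals, region_dates(config))
  })
}

#' Place a station network with vulnerability-biased siting
#'
#' Stations land in tracts with probability proportional to
#' `exp(-siting_bias * SVI)`, then uniformly within the tract. Each station
#' receives an operational mask built from geometric-length outage blocks, so
#' some stations pass and some fail a 99% completeness screen by
#' construction.
#'
#' @param units Exposure-unit tibble from [generate_units()] (needs `svi` and
#'   `geometry`).
#' @param elevation Optional elevation raster (unused by the default siting
#'   model; accepted for signature stability).
#' @param config A [region_config()].
#' @return A tibble with `station_id`, `x`, `y`, `tract_id`, list-column
#'   `operational` (logical per day) and `completeness`.
#' @export
place_stations <- function(units, elevation = NULL, config) {
  stopifnot(inherits(config, "region_config"))
  if (config$n_stations < 1) stop("invalid region_config: `n_stations` must be >= 1", call. = FALSE)
  if (!"svi" %in% names(units)) stop("units must carry an `svi` column", call. = FALSE)
  with_seed(child_seed(config$seed, 3), {
    prob <- exp(-config$siting_bias * units$svi)
    tract <- sample.int(nrow(units), config$n_stations, replace = TRUE, prob = prob)
    tract_km <- config$region_size_km / config$n_tracts_side
    xmin <- vapply(units$geometry[tract], function(r) min(r[, 1]), numeric(1))
    ymin <- vapply(units$geometry[tract], function(r) min(r[, 2]), numeric(1))
    x <- xmin + stats::runif(config$n_stations) * tract_km
    y <- ymin + stats::runif(config$n_stations) * tract_km

    # Heterogeneous station quality: about a third of stations are
    # high-quality (outage rate missing_rate / 20), the rest run at the full
    # missing_rate, so a 99% completeness screen retains some stations and
    # rejects others by construction. Outages come in geometric blocks.
    p_exit <- 1 / config$outage_mean_len
    high_quality <- stats::runif(config$n_stations) < 1 / 3
    rate <- ifelse(high_quality, config$missing_rate / 20, config$missing_rate)
    operational <- purrr::map(seq_len(config$n_stations), function(s) {
      m <- min(rate[s], 0.999)
      p_enter <- m * p_exit / (1 - m)
      u <- stats::runif(config$n_days)
      op <- logical(config$n_days)
      state <- TRUE
      for (d in seq_len(config$n_days)) {
        state <- if (state) u[d] >= p_enter else u[d] < p_exit
        op[d] <- state
      }
      op
    })
    tibble::tibble(
      station_id = sprintf("S%03d", seq_len(config$n_stations)),
      x = x, y = y,
      tract_id = units$unit_id[tract],
      operational = operational,
      completeness = vapply(operational, mean, numeric(1))
    )
  })
}

#' Observe the truth field at station locations
#'
#' Each station records the truth value of its containing fine-grid cell plus
#' additive Gaussian gauge noise (clamped at zero), is missing during outage
#' blocks, and carries a QC flag on a random fraction of observed days.
#'
#' @param truth Fine [daily_grid()] from [generate_truth_field()].
#' @param stations Station tibble from [place_stations()].
#' @param config A [region_config()].
#' @return Long tibble: `station_id`, `date`, `prcp_mm` (NA when offline),
#'   `qc_flag` (logical).
#' @export
observe_stations <- function(truth, stations, config) {
  with_seed(child_seed(config$seed, 4), {
    nd <- dim(truth$values)[1]
    dates <- truth$dates
    out <- purrr::map(seq_len(nrow(stations)), function(s) {
      idx <- cell_index(truth$spec, stations$x[s], stations$y[s])
      v <- truth$values[, idx$row, idx$col]
      if (config$obs_noise_sd > 0) {
        v <- pmax(0, v + stats::rnorm(nd, 0, config$obs_noise_sd))
      }
      op <- stations$operational[[s]]
      v[!op] <- NA_real_
      flag <- stats::runif(nd) < config$qc_flag_rate & op
      tibble::tibble(
        station_id = stations$station_id[s],
        date = dates, prcp_mm = v, qc_flag = flag
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Derive the two gridded products from truth and station observations
#'
#' The interpolated product mimics a station-driven interpolation surface:
#' inverse-distance-weighted (power 2) interpolation of each day's available
#' (non-missing, unflagged) station values onto the fine grid; a station
#' sitting exactly on a cell center reproduces its value there. The
#' assimilation product mimics a coarse model-assimilation field: the truth
#' block-averaged to the coarse grid, perturbed with mean-one multiplicative
#' lognormal noise, then disaggregated into 24 hourly layers by random
#' simplex weights that sum exactly to the daily value.
#'
#' @param truth Fine [daily_grid()].
#' @param stations Station tibble from [place_stations()].
#' @param station_obs Observation tibble from [observe_stations()].
#' @param config A [region_config()].
#' @return List with `interp_product` (fine [daily_grid()]) and
#'   `assim_product` (coarse [hourly_grid()]).
#' @export
derive_products <- function(truth, stations, station_obs, config) {
  with_seed(child_seed(config$seed, 5), {
    spec <- fine_spec(config)
    nd <- dim(truth$values)[1]
    ncell <- spec$ny * spec$nx
    centers <- expand.grid(y = cell_centers_y(spec), x = cell_centers_x(spec))
    # distances: stations x cells (cells in column-major (row, col) order)
    D2 <- distance_matrix(cbind(stations$x, stations$y), cbind(centers$x, centers$y))^2
    W <- 1 / pmax(D2, 1e-12)
    exact <- D2 < 1e-12

    obs <- tidyr::pivot_wider(
      dplyr::mutate(station_obs, prcp_mm = ifelse(.data$qc_flag, NA_real_, .data$prcp_mm)),
      id_cols = "date", names_from = "station_id", values_from = "prcp_mm"
    )
    obs <- obs[order(obs$date), ]
    vmat <- as.matrix(obs[, stations$station_id, drop = FALSE])

    interp_vals <- array(NA_real_, dim = c(nd, spec$ny, spec$nx))
    for (d in seq_len(nd)) {
      v <- vmat[d, ]
      avail <- !is.na(v)
      if (!any(avail)) {
        stop(sprintf("no operating station with data on day %s", truth$dates[d]), call. = FALSE)
      }
      wa <- W[avail, , drop = FALSE]
      est <- colSums(wa * v[avail]) / colSums(wa)
      ea <- exact[avail, , drop = FALSE]
      hit <- which(colSums(ea) > 0)
      if (length(hit)) {
        vi <- v[avail]
        est[hit] <- vapply(hit, function(k) vi[which(ea[, k])[1]], numeric(1))
      }
      interp_vals[d, , ] <- matrix(est, spec$ny, spec$nx)
    }
    interp_product <- daily_grid(spec, pmax(interp_vals, 0), truth$dates)

    cs <- coarse_spec(config)
    f <- config$coarse_factor
    daily_coarse <- array(0, dim = c(nd, cs$ny, cs$nx))
    for (ci in seq_len(cs$ny)) {
      for (cj in seq_len(cs$nx)) {
        rows <- ((ci - 1) * f + 1):(ci * f)
        cols <- ((cj - 1) * f + 1):(cj * f)
        block <- truth$values[, rows, cols, drop = FALSE]
        daily_coarse[, ci, cj] <- apply(block, 1, mean)
      }
    }
    if (config$assim_noise_sd > 0) {
      noise <- exp(stats::rnorm(
        length(daily_coarse),
        mean = -config$assim_noise_sd^2 / 2, sd = config$assim_noise_sd
      ))
      daily_coarse <- daily_coarse * noise
    }
    hourly <- array(0, dim = c(nd, 24, cs$ny, cs$nx))
    wts <- array(stats::rexp(nd * 24 * cs$ny * cs$nx), dim = c(nd, 24, cs$ny, cs$nx))
    tot <- apply(wts, c(1, 3, 4), sum)
    for (h in seq_len(24)) {
      hourly[, h, , ] <- daily_coarse * wts[, h, , ] / tot
    }
    assim_product <- hourly_grid(cs, hourly, truth$dates)

    list(interp_product = interp_product, assim_product = assim_product)
  })
}

#' Generate a complete synthetic study region
#'
#' Runs the full generative model: tracts with demographics, elevation and
#' SVI; a fine-grid truth precipitation field; a biased station network with
#' outages and QC flags; and the two derived gridded products. Deterministic
#' given the config (a single seed fans out to per-stage child seeds, so each
#' stage is individually reproducible).
#'
#' @param config A [region_config()].
#' @param products Generate the derived gridded products (default TRUE); set
#'   FALSE to skip the interpolation/assimilation stage when only units,
#'   stations and observations are needed.
#' @return An object of class `synthetic_region`: list with `config`,
#'   `units`, `elevation`, `truth`, `stations`, `station_obs`,
#'   `interp_product`, `assim_product`.
#' @examples
#' region <- generate_region(region_config(n_tracts_side = 3, n_days = 30,
#'                                         n_stations = 4, seed = 7))
#' region$units
#' @export
generate_region <- function(config, products = TRUE) {
  stopifnot(inherits(config, "region_config"))
  ue <- generate_units(config)
  truth <- generate_truth_field(config)
  stations <- place_stations(ue$units, ue$elevation, config)
  station_obs <- observe_stations(truth, stations, config)
  prod <- if (products) {
    derive_products(truth, stations, station_obs, config)
  } else {
    list(interp_product = NULL, assim_product = NULL)
  }
  structure(
    list(
      config = config, units = ue$units, elevation = ue$elevation,
      truth = truth, stations = stations, station_obs = station_obs,
      interp_product = prod$interp_product, assim_product = prod$assim_product
    ),
    class = "synthetic_region"
  )
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf(
    "<synthetic_region> %d tracts, %d stations, %d days (seed %d)\n",
    nrow(x$units), nrow(x$stations), x$config$n_days, x$config$seed
  ))
  invisible(x)
}
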