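#' EPE definitions
#'
#' Two operational definitions of an extreme precipitation event (EPE): a
#' locally specific one — daily precipitation strictly exceeding the local
#' 99th percentile of wet-day values — and an absolute one — daily
#' precipitation of more than one inch (25.4 mm).
#'
#' @param kind `"percentile_99"` or `"absolute"`.
#' @param absolute_threshold_mm Threshold for the absolute kind (default
#'   25.4 mm = 1 inch).
#' @return A list of class `epe_definition`.
#' @export
epe_definition <- function(kind = c("percentile_99", "absolute"),
                           absolute_threshold_mm = 25.4) {
  kind <- match.arg(kind)
  if (kind == "absolute" && absolute_threshold_mm <= 0) {
    stop("absolute_threshold_mm must be positive", call. = FALSE)
  }
  structure(list(kind = kind, absolute_threshold_mm = absolute_threshold_mm),
    class = "epe_definition"
  )
}

#' Classify daily values against an EPE threshold
#'
#' Strict exceedance: 1 iff the value is strictly greater than the threshold
#' ("more than one inch"); exactly-at-threshold days are 0. Missing values
#' propagate as missing indicators.
#'
#' @param values Numeric daily precipitation (mm).
#' @param threshold_mm Threshold (mm).
#' @return Integer vector in \{0, 1, NA\}.
#' @export
classify_epe <- function(values, threshold_mm) {
  if (is.na(threshold_mm)) stop("threshold must be defined", call. = FALSE)
  as.integer(values > threshold_mm)
}

#' Unit-by-day EPE indicator matrix
#'
#' @param indicator Integer matrix (units x days) in \{0, 1, NA\}.
#' @param unit_ids,dates Row and column identities.
#' @param source Data-source label (e.g. `"station"`, `"interp"`, `"assim"`).
#' @param definition An [epe_definition()].
#' @return Object of class `epe_matrix`.
#' @export
epe_matrix <- function(indicator, unit_ids, dates, source, definition) {
  stopifnot(
    nrow(indicator) == length(unit_ids),
    ncol(indicator) == length(dates)
  )
  rownames(indicator) <- unit_ids
  structure(
    list(
      indicator = indicator, unit_ids = unit_ids, dates = as.Date(dates),
      source = source, definition = definition
    ),
    class = "epe_matrix"
  )
}

#' @export
print.epe_matrix <- function(x, ...) {
  cat(sprintf(
    "<epe_matrix> %s / %s: %d units x %d days, %d EPE unit-days\n",
    x$source, x$definition$kind, length(x$unit_ids), length(x$dates),
    sum(x$indicator == 1L, na.rm = TRUE)
  ))
  invisible(x)
}

#' Tidy an EPE matrix into long format
#'
#' @param x An [epe_matrix()].
#' @param ... Unused.
#' @return Tibble `unit_id`, `date`, `source`, `definition`, `epe`.
#' @export
tidy.epe_matrix <- function(x, ...) {
  tibble::tibble(
    unit_id = rep(x$unit_ids, times = length(x$dates)),
    date = rep(x$dates, each = length(x$unit_ids)),
    source = x$source,
    definition = x$definition$kind,
    epe = as.integer(x$indicator)
  )
}

# long (unit_id, date, prcp_mm) -> units x days value matrix
series_to_matrix <- function(series, unit_ids, dates) {
  m <- matrix(NA_real_, length(unit_ids), length(dates))
  i <- match(series$unit_id, unit_ids)
  j <- match(series$date, dates)
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- series$prcp_mm[ok]
  m
}

#' Build EPE indicator matrices for several sources and definitions
#'
#' Takes per-unit daily series for each data source (identical schema
#' regardless of origin) plus per-unit percentile thresholds per source, and
#' emits one binary matrix per (source, definition) combination. All sources
#' must cover the same units and date range.
#'
#' @param series_list Named list of long series tibbles (`unit_id`, `date`,
#'   `prcp_mm`), one per source.
#' @param thresholds_list Named list (same names) of tibbles `unit_id`,
#'   `threshold_mm` used by the percentile definition.
#' @param definitions List of [epe_definition()]s (default: both).
#' @param quiet Suppress per-matrix EPE count messages.
#' @return Named list of [epe_matrix()] objects, names `source.definition`.
#' @export
build_epe_matrices <- function(series_list, thresholds_list,
                               definitions = list(
                                 epe_definition("percentile_99"),
                                 epe_definition("absolute")
                               ),
                               quiet = FALSE) {
  stopifnot(length(series_list) >= 1, !is.null(names(series_list)))
  dates <- sort(unique(series_list[[1]]$date))
  unit_ids <- unique(series_list[[1]]$unit_id)
  for (nm in names(series_list)) {
    s <- series_list[[nm]]
    if (!setequal(unique(s$date), dates) || !setequal(unique(s$unit_id), unit_ids)) {
      stop(sprintf("source '%s' is not aligned with the others (units/dates differ)", nm),
        call. = FALSE
      )
    }
  }
  out <- list()
  for (nm in names(series_list)) {
    vals <- series_to_matrix(series_list[[nm]], unit_ids, dates)
    for (def in definitions) {
      ind <- matrix(NA_integer_, length(unit_ids), length(dates))
      if (def$kind == "absolute") {
        ind[] <- as.integer(vals > def$absolute_threshold_mm)
      } else {
        thr <- thresholds_list[[nm]]
        if (is.null(thr)) stop(sprintf("no thresholds supplied for source '%s'", nm), call. = FALSE)
        tvec <- thr$threshold_mm[match(unit_ids, thr$unit_id)]
        ind[] <- as.integer(vals > tvec) # tvec recycles down rows (units)
        ind[is.na(tvec), ] <- NA_integer_
      }
      m <- epe_matrix(ind, unit_ids, dates, nm, def)
      key <- paste(nm, def$kind, sep = ".")
      if (!quiet) {
        message(sprintf(
          "EPE matrix %s: %d EPE unit-days", key,
          sum(ind == 1L, na.rm = TRUE)
        ))
      }
      out[[key]] <- m
    }
  }
  out
}
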