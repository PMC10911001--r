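#' Sociodemographic stratification of exposure units
#'
#' Builds the stratification schemes used in the agreement analysis:
#' dichotomous majority flags (share strictly > 50%), income class (low
#' income when the poverty share exceeds 20%, strict by default since
#' published definitions disagree between > and >=), SVI quartile bins —
#' very low (0.00-0.25\], low (0.25-0.50\], high (0.50-0.75\], very high
#' (0.75-1.00\], right-closed — and the urbanicity label. Units missing an
#' attribute are flagged unclassifiable (`NA`) for that scheme only.
#'
#' @param units Exposure-unit tibble with the demographic columns.
#' @param poverty_op Comparison operator for the low-income cutoff
#'   (default `` `>` ``; pass `` `>=` `` for the inclusive variant).
#' @return Tibble `unit_id` plus one column per scheme: `majority_minority`,
#'   `majority_black`, `majority_native_american`, `majority_asian`,
#'   `majority_hispanic` (logical), `income_class`, `svi_bin`, `urbanicity`.
#' @export
categorize_units <- function(units, poverty_op = `>`) {
  flag <- function(x) ifelse(is.na(x), NA, x > 50)
  svi_bin <- cut(units$svi,
    breaks = c(0, 0.25, 0.5, 0.75, 1),
    labels = c("very low", "low", "high", "very high"),
    include.lowest = TRUE, right = TRUE
  )
  tibble::tibble(
    unit_id = units$unit_id,
    majority_minority = flag(units$pct_minority),
    majority_black = flag(units$pct_black),
    majority_native_american = flag(units$pct_native_american),
    majority_asian = flag(units$pct_asian),
    majority_hispanic = flag(units$pct_hispanic),
    income_class = ifelse(
      is.na(units$pct_poverty), NA_character_,
      ifelse(poverty_op(units$pct_poverty, 20), "low income", "not low income")
    ),
    svi_bin = as.character(svi_bin),
    urbanicity = units$urbanicity
  )
}

#' Topographic prominence of a polygon
#'
#' Difference between the highest and lowest elevation among raster cells
#' intersecting the polygon, after block-aggregating the elevation raster by
#' `agg_factor` (mean within blocks) to emulate working at a coarsened
#' resolution.
#'
#' @param ring Two-column polygon vertex matrix.
#' @param elevation List with `spec` ([grid_spec()]) and matrix `values` (km).
#' @param agg_factor Integer block size for aggregation (default 1 = none);
#'   must divide both raster dimensions.
#' @return Prominence in the raster's units (km).
#' @export
prominence_from_elevation <- function(ring, elevation, agg_factor = 1) {
  spec <- elevation$spec
  values <- elevation$values
  if (agg_factor > 1) {
    if (spec$ny %% agg_factor != 0 || spec$nx %% agg_factor != 0) {
      stop("agg_factor must divide raster dimensions", call. = FALSE)
    }
    ny2 <- spec$ny %/% agg_factor
    nx2 <- spec$nx %/% agg_factor
    agg <- matrix(0, ny2, nx2)
    for (i in seq_len(ny2)) {
      for (j in seq_len(nx2)) {
        agg[i, j] <- mean(values[
          ((i - 1) * agg_factor + 1):(i * agg_factor),
          ((j - 1) * agg_factor + 1):(j * agg_factor)
        ])
      }
    }
    values <- agg
    spec <- grid_spec(spec$x0, spec$y0, spec$dx * agg_factor, spec$dy * agg_factor, nx2, ny2)
  }
  w <- polygon_cell_weights(ring, spec)
  if (nrow(w) == 0) stop("polygon does not intersect elevation raster", call. = FALSE)
  v <- values[cbind(w$row, w$col)]
  max(v) - min(v)
}

#' Covariate-matched strata around a referent group
#'
#' Splits the non-referent units into those matched to the referent group —
#' population density and topographic prominence both within one sample
#' standard deviation of the referent mean (closed intervals) — and the
#' unmatched remainder.
#'
#' @param units Exposure-unit tibble with `pop_density` and `prominence_km`.
#' @param referent_flag Logical vector (or unquoted column name resolved in
#'   `units`) marking the referent group; needs >= 2 referent units.
#' @return Tibble `unit_id`, `match_group` in
#'   \{"referent", "matched", "unmatched"\}.
#' @export
match_units <- function(units, referent_flag) {
  flag <- if (is.logical(referent_flag)) referent_flag else units[[referent_flag]]
  if (sum(flag, na.rm = TRUE) < 2) {
    stop("referent group must contain at least 2 units", call. = FALSE)
  }
  flag[is.na(flag)] <- FALSE
  ref <- units[flag, ]
  mu_d <- mean(ref$pop_density)
  sd_d <- stats::sd(ref$pop_density)
  mu_p <- mean(ref$prominence_km)
  sd_p <- stats::sd(ref$prominence_km)
  in_band <- function(x, mu, s) x >= mu - s & x <= mu + s
  matched <- !flag &
    in_band(units$pop_density, mu_d, sd_d) &
    in_band(units$prominence_km, mu_p, sd_p)
  tibble::tibble(
    unit_id = units$unit_id,
    match_group = dplyr::case_when(
      flag ~ "referent",
      matched ~ "matched",
      TRUE ~ "unmatched"
    )
  )
}

#' Regress station distance on sociogeographic covariates
#'
#' Ordinary least-squares fits of mean daily distance to the nearest station
#' (km) on (1) Native American share, (2) adding topographic prominence,
#' (3) adding population density, (4) all three. Shares enter as proportions
#' (0-1) so the share coefficient is km per unit share. Coefficients carry
#' classical normal-theory 95% CIs.
#'
#' @param profiles Tibble from [distance_profile()].
#' @param units Exposure-unit tibble.
#' @param models Integer subset of 1:4 (default all).
#' @return Tibble `model`, `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
distance_regression <- function(profiles, units, models = 1:4) {
  dat <- dplyr::inner_join(profiles, units, by = "unit_id") |>
    dplyr::transmute(
      distance_km = .data$mean_daily_distance_km,
      native_share = .data$pct_native_american / 100,
      prominence_km = .data$prominence_km,
      pop_density = .data$pop_density
    )
  forms <- list(
    distance_km ~ native_share,
    distance_km ~ native_share + prominence_km,
    distance_km ~ native_share + pop_density,
    distance_km ~ native_share + prominence_km + pop_density
  )
  purrr::map_dfr(models, function(m) {
    f <- forms[[m]]
    p <- length(attr(stats::terms(f), "term.labels"))
    if (nrow(dat) < p + 1) stop("too few units for the requested model", call. = FALSE)
    fit <- stats::lm(f, data = dat)
    if (anyNA(stats::coef(fit))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop(sprintf("rank-deficient design: collinear term(s) %s", paste(bad, collapse = ", ")),
        call. = FALSE
      )
    }
    ci <- suppressWarnings(stats::confint(fit, level = 0.95)) # NaN at 0 residual df
    sm <- summary(fit)$coefficients
    tibble::tibble(
      model = m,
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      std.error = unname(sm[, "Std. Error"]),
      conf.low = unname(ci[, 1]),
      conf.high = unname(ci[, 2]),
      p.value = unname(sm[, "Pr(>|t|)"])
    )
  })
}

#' One-way analysis of variance across groups
#'
#' Classical between/within decomposition with the F reference distribution,
#' used to compare unit characteristics across station-distance strata. The
#' degenerate zero-within-variance case (identical values within every group,
#' differing across) is reported as an infinite F with p = 0 and a note
#' rather than an error.
#'
#' @param values Numeric response per unit.
#' @param groups Grouping factor (>= 2 non-empty groups).
#' @return One-row tibble `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `note`.
#' @export
one_way_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) stop("one-way ANOVA needs at least 2 groups", call. = FALSE)
  n <- length(values)
  if (n < k + 1) stop("too few observations for within-group df", call. = FALSE)
  gm <- tapply(values, groups, mean)
  ss_between <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- k - 1
  df_w <- n - k
  if (ss_within == 0) {
    if (ss_between == 0) stop("all values identical: ANOVA undefined", call. = FALSE)
    return(tibble::tibble(
      f_statistic = Inf, df_between = df_b, df_within = df_w,
      p_value = 0, note = "zero within-group variance"
    ))
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  tibble::tibble(
    f_statistic = f, df_between = df_b, df_within = df_w,
    p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
    note = NA_character_
  )
}

#' False positives and negatives against a reference source
#'
#' Counts comparator EPEs on reference non-EPE days (false positives) and
#' comparator non-EPEs on reference EPE days (false negatives) over a unit
#' subset, both as totals and normalized per tract. The reference source is
#' a comparison anchor only, not ground truth: no claim is made that it is
#' the most accurate measurement (recorded in the `disclaimer` attribute).
#'
#' @param reference,comparator Aligned [epe_matrix()] objects.
#' @param unit_subset Character vector of unit ids (non-empty).
#' @return One-row tibble: `n_units`, `reference_epes`, `false_positives`,
#'   `false_negatives`, `fp_per_tract`, `fn_per_tract`.
#' @export
confusion_counts <- function(reference, comparator, unit_subset) {
  if (length(unit_subset) == 0) stop("unit subset must be non-empty", call. = FALSE)
  if (!identical(reference$dates, comparator$dates) ||
    !identical(reference$unit_ids, comparator$unit_ids)) {
    stop("EPE matrices are not aligned", call. = FALSE)
  }
  keep <- reference$unit_ids %in% unit_subset
  if (!any(keep)) stop("no units of the subset found in matrices", call. = FALSE)
  r <- reference$indicator[keep, , drop = FALSE]
  c_ <- comparator$indicator[keep, , drop = FALSE]
  ok <- !is.na(r) & !is.na(c_)
  fp <- sum(c_ == 1L & r == 0L & ok)
  fn <- sum(c_ == 0L & r == 1L & ok)
  nu <- sum(keep)
  out <- tibble::tibble(
    n_units = nu,
    reference_epes = sum(r == 1L & ok),
    false_positives = fp,
    false_negatives = fn,
    fp_per_tract = fp / nu,
    fn_per_tract = fn / nu
  )
  attr(out, "disclaimer") <- paste(
    "The reference source anchors the comparison only;",
    "no claim is made that it is the most accurate measurement."
  )
  out
}
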