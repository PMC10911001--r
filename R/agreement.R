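#' 2x2 contingency table over complete pairs
#'
#' Cross-tabulates two aligned binary indicator vectors, dropping any pair
#' with a missing member (pairwise-complete convention).
#'
#' @param a,b Integer/logical vectors in \{0, 1, NA\} of equal length.
#' @return Object of class `contingency_2x2`: list with `n11`, `n10`, `n01`,
#'   `n00`, `n` (counts: first index rater A, second rater B).
#' @export
contingency <- function(a, b) {
  if (length(a) != length(b)) stop("series must be aligned (equal length)", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  a <- as.integer(a[ok])
  b <- as.integer(b[ok])
  n <- length(a)
  if (n == 0) stop("no complete pairs", call. = FALSE)
  structure(
    list(
      n11 = sum(a == 1L & b == 1L),
      n10 = sum(a == 1L & b == 0L),
      n01 = sum(a == 0L & b == 1L),
      n00 = sum(a == 0L & b == 0L),
      n = n
    ),
    class = "contingency_2x2"
  )
}

as_contingency <- function(n11, n10, n01, n00) {
  structure(
    list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, n = n11 + n10 + n01 + n00),
    class = "contingency_2x2"
  )
}

#' Landis-Koch interpretation of a kappa value
#'
#' Maps kappa to the conventional qualitative bands: < 0 poor, 0.00-0.20
#' slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial,
#' 0.81-1.00 almost perfect. Intervals are closed on the right (a kappa of
#' exactly 0.20 is "slight"). Missing/undefined kappa maps to "undefined".
#'
#' @param kappa Numeric vector of kappa values.
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(kappa) {
  eps <- 1e-9 # bands are defined on printed 2-decimal cut-points
  dplyr::case_when(
    is.na(kappa) ~ "undefined",
    kappa < 0 ~ "poor",
    kappa <= 0.20 + eps ~ "slight",
    kappa <= 0.40 + eps ~ "fair",
    kappa <= 0.60 + eps ~ "moderate",
    kappa <= 0.80 + eps ~ "substantial",
    TRUE ~ "almost perfect"
  )
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' observed agreement and p_e the marginal-product chance agreement. The
#' standard error uses the asymptotic large-sample variance of Fleiss, Cohen
#' and Everitt (1969); the 95% CI is the normal approximation
#' kappa +/- 1.96 se. When chance agreement is 1 (both raters constant),
#' kappa is undefined and reported missing.
#'
#' @param a A `contingency_2x2`, an `epe_matrix`, or a binary vector.
#' @param b Second binary vector or `epe_matrix` when `a` is one.
#' @return Object of class `kappa_result`.
#' @examples
#' cohen_kappa(c(1, 0, 1, 0, 1), c(1, 0, 0, 0, 1))
#' @export
cohen_kappa <- function(a, b = NULL) {
  t <- if (inherits(a, "contingency_2x2")) {
    a
  } else if (inherits(a, "epe_matrix")) {
    contingency(as.vector(a$indicator), as.vector(b$indicator))
  } else {
    contingency(a, b)
  }
  p11 <- t$n11 / t$n
  p10 <- t$n10 / t$n
  p01 <- t$n01 / t$n
  p00 <- t$n00 / t$n
  pa1 <- p11 + p10
  pb1 <- p11 + p01
  p_o <- p11 + p00
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)

  if (p_e >= 1) {
    res <- list(
      kappa = NA_real_, p_o = p_o, p_e = p_e, se = NA_real_,
      ci_lo = NA_real_, ci_hi = NA_real_, n = t$n, counts = t,
      label = "undefined", defined = FALSE
    )
    return(structure(res, class = "kappa_result"))
  }

  kappa <- (p_o - p_e) / (1 - p_e)

  # Fleiss, Cohen & Everitt asymptotic variance for two categories.
  # p[i,j]: rows rater A (1 then 0), cols rater B.
  p <- matrix(c(p11, p10, p01, p00), 2, 2, byrow = TRUE)
  pa <- rowSums(p) # A marginals for categories (1, 0)
  pb <- colSums(p) # B marginals
  a_term <- p[1, 1] * (1 - (pa[1] + pb[1]) * (1 - kappa))^2 +
    p[2, 2] * (1 - (pa[2] + pb[2]) * (1 - kappa))^2
  b_term <- (1 - kappa)^2 * (p[1, 2] * (pb[1] + pa[2])^2 + p[2, 1] * (pb[2] + pa[1])^2)
  c_term <- (kappa - p_e * (1 - kappa))^2
  v <- (a_term + b_term - c_term) / (t$n * (1 - p_e)^2)
  se <- sqrt(max(v, 0))

  structure(
    list(
      kappa = kappa, p_o = p_o, p_e = p_e, se = se,
      ci_lo = kappa - 1.96 * se, ci_hi = kappa + 1.96 * se,
      n = t$n, counts = t, label = interpret_kappa(kappa), defined = TRUE
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Cohen's kappa: undefined (constant raters), n = %d\n", x$n))
  } else {
    cat(sprintf(
      "Cohen's kappa: %.3f (95%% CI %.3f-%.3f), n = %d, %s\n",
      x$kappa, x$ci_lo, x$ci_hi, x$n, x$label
    ))
  }
  invisible(x)
}

#' Tidy a kappa result
#'
#' @param x A `kappa_result`.
#' @param ... Unused.
#' @return One-row tibble: `kappa`, `se`, `ci_lo`, `ci_hi`, `p_o`, `p_e`,
#'   `n`, `label`, `defined`.
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, se = x$se, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    p_o = x$p_o, p_e = x$p_e, n = x$n, label = x$label, defined = x$defined
  )
}

#' @rdname tidy.kappa_result
#' @export
glance.kappa_result <- function(x, ...) tidy.kappa_result(x)

# Pool unit-days of two aligned EPE matrices restricted to given units/dates.
pooled_kappa <- function(mA, mB, units = NULL, date_keep = NULL) {
  ia <- mA$indicator
  ib <- mB$indicator
  if (!identical(dim(ia), dim(ib)) || !identical(mA$dates, mB$dates) ||
    !identical(mA$unit_ids, mB$unit_ids)) {
    stop("EPE matrices are not aligned", call. = FALSE)
  }
  if (!is.null(units)) {
    keep <- mA$unit_ids %in% units
    ia <- ia[keep, , drop = FALSE]
    ib <- ib[keep, , drop = FALSE]
  }
  if (!is.null(date_keep)) {
    ia <- ia[, date_keep, drop = FALSE]
    ib <- ib[, date_keep, drop = FALSE]
  }
  cohen_kappa(as.vector(ia), as.vector(ib))
}

#' Annual kappa series
#'
#' Kappa over unit-days restricted to each calendar year, the basis of
#' temporal-trend displays of agreement.
#'
#' @param mA,mB Aligned [epe_matrix()] objects.
#' @return Tibble with one row per year: `year` plus [tidy.kappa_result()]
#'   columns. Years with no complete pair are flagged undefined.
#' @export
annual_kappa <- function(mA, mB) {
  years <- as.integer(format(mA$dates, "%Y"))
  purrr::map_dfr(sort(unique(years)), function(y) {
    keep <- years == y
    res <- tryCatch(
      pooled_kappa(mA, mB, date_keep = keep),
      error = function(e) NULL
    )
    row <- if (is.null(res)) {
      tibble::tibble(
        kappa = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        p_o = NA_real_, p_e = NA_real_, n = 0L, label = "undefined", defined = FALSE
      )
    } else {
      tidy.kappa_result(res)
    }
    dplyr::bind_cols(tibble::tibble(year = y), row)
  })
}

#' Stratified kappa
#'
#' Pools the unit-days of each stratum of units into one 2x2 table and
#' computes kappa per stratum — the pooled-count convention implied by
#' CONUS-scale kappas with very narrow CIs. A per-unit mode (`pooled =
#' FALSE`) instead averages per-unit kappas within each stratum.
#'
#' @param mA,mB Aligned [epe_matrix()] objects.
#' @param strata Tibble `unit_id`, `stratum` (or a named vector
#'   unit_id -> stratum). Units with missing stratum are dropped.
#' @param pooled Pool unit-days per stratum (default) or average per-unit
#'   kappas.
#' @return Tibble with one row per stratum.
#' @export
stratified_kappa <- function(mA, mB, strata, pooled = TRUE) {
  if (!is.data.frame(strata)) {
    strata <- tibble::tibble(unit_id = names(strata), stratum = unname(strata))
  }
  strata <- strata[!is.na(strata$stratum), , drop = FALSE]
  purrr::map_dfr(unique(strata$stratum), function(s) {
    ids <- strata$unit_id[strata$stratum == s]
    row <- if (pooled) {
      res <- tryCatch(pooled_kappa(mA, mB, units = ids), error = function(e) NULL)
      if (is.null(res)) {
        tibble::tibble(
          kappa = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          p_o = NA_real_, p_e = NA_real_, n = 0L, label = "undefined", defined = FALSE
        )
      } else {
        tidy.kappa_result(res)
      }
    } else {
      ks <- purrr::map_dbl(ids, function(u) {
        res <- tryCatch(pooled_kappa(mA, mB, units = u), error = function(e) NULL)
        if (is.null(res) || !res$defined) NA_real_ else res$kappa
      })
      tibble::tibble(
        kappa = mean(ks, na.rm = TRUE), se = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, p_o = NA_real_, p_e = NA_real_,
        n = sum(!is.na(ks)), label = interpret_kappa(mean(ks, na.rm = TRUE)),
        defined = any(!is.na(ks))
      )
    }
    dplyr::bind_cols(tibble::tibble(stratum = s), row)
  })
}

#' Pairwise agreement table across sources
#'
#' Pooled kappa for every two-way comparison of the supplied EPE matrices
#' (same definition), mirroring the headline agreement-table layout.
#'
#' @param matrices Named list of aligned [epe_matrix()] objects sharing one
#'   definition.
#' @return Tibble `comparison` plus kappa columns.
#' @export
agreement_table <- function(matrices) {
  nms <- names(matrices)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    res <- pooled_kappa(matrices[[p[1]]], matrices[[p[2]]])
    dplyr::bind_cols(
      tibble::tibble(comparison = paste(p, collapse = " vs ")),
      tidy.kappa_result(res)
    )
  })
}
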