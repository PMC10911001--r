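#' Plot an annual kappa series
#'
#' Point estimates with 95% confidence bars per calendar year, one panel per
#' definition if present.
#'
#' @param annual Tibble from [annual_kappa()] (optionally with a
#'   `definition` or `comparison` column for colour).
#' @return A ggplot object.
#' @export
plot_annual_kappa <- function(annual) {
  aes_args <- ggplot2::aes(x = .data$year, y = .data$kappa)
  p <- ggplot2::ggplot(annual, aes_args)
  if ("comparison" %in% names(annual)) {
    p <- p + ggplot2::aes(colour = .data$comparison)
  }
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Cohen's kappa") +
    ggplot2::theme_minimal()
}

#' Plot stratified kappa estimates
#'
#' @param stratified Tibble from [stratified_kappa()] (optionally with
#'   `scheme`/`comparison` columns from the pipeline, used for faceting).
#' @return A ggplot object.
#' @export
plot_stratified_kappa <- function(stratified) {
  p <- ggplot2::ggplot(
    stratified,
    ggplot2::aes(x = .data$stratum, y = .data$kappa)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::labs(x = NULL, y = "Cohen's kappa") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (all(c("scheme", "comparison") %in% names(stratified))) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$comparison),
      cols = ggplot2::vars(.data$scheme), scales = "free_x"
    )
  }
  p
}

#' Map a tract attribute over the synthetic region
#'
#' Tract polygons filled by any numeric or categorical unit attribute, with
#' station locations overlaid when supplied.
#'
#' @param units Exposure-unit tibble with a `geometry` list-column.
#' @param fill Name of the attribute column to fill by.
#' @param stations Optional station tibble to overlay.
#' @return A ggplot object.
#' @export
plot_region <- function(units, fill = "svi", stations = NULL) {
  poly <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    ring <- units$geometry[[i]]
    tibble::tibble(
      unit_id = units$unit_id[i],
      x = ring[, 1], y = ring[, 2],
      value = units[[fill]][i]
    )
  })
  p <- ggplot2::ggplot(poly, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(
      ggplot2::aes(group = .data$unit_id, fill = .data$value),
      colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km", fill = fill) +
    ggplot2::theme_minimal()
  if (!is.null(stations)) {
    p <- p + ggplot2::geom_point(
      data = stations, ggplot2::aes(x = .data$x, y = .data$y),
      shape = 17, size = 2, colour = "black"
    )
  }
  p
}

#' Autoplot method for synthetic regions
#'
#' SVI map with station overlay — a quick visual check that biased siting
#' avoids high-vulnerability tracts.
#'
#' @param object A `synthetic_region`.
#' @param ... Passed to [plot_region()].
#' @return A ggplot object.
#' @export
autoplot.synthetic_region <- function(object, ...) {
  plot_region(object$units, stations = object$stations, ...)
}
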