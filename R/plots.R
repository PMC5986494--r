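#' Cost-effectiveness plane
#'
#' Scatter of Monte Carlo iterations with incremental HALYs on the horizontal
#' axis and incremental net cost on the vertical axis, quadrant axes through
#' the origin, the willingness-to-pay line of slope `wtp` A$/HALY, and
#' quadrant-share annotations.
#'
#' @param psa A `fopl_psa` object or an iterations tibble with `halys` and
#'   `net_cost` columns.
#' @param wtp Willingness-to-pay threshold (A$/HALY) drawn as the dashed
#'   line; defaults to the PSA's own threshold when available.
#' @return A ggplot object.
#' @examples
#' psa <- run_psa(fixture_inputs(800), n_iter = 10, seed = 1)
#' plot_ce_plane(psa)
#' @export
plot_ce_plane <- function(psa, wtp = NULL) {
  if (inherits(psa, "fopl_psa")) {
    wtp <- wtp %||% psa$wtp
    it <- psa$iterations
  } else {
    wtp <- wtp %||% 50000
    it <- psa
  }
  it <- it[!is.na(it$halys), ]
  shares <- table(factor(ce_quadrant(it$halys, it$net_cost),
                         levels = c("NE", "NW", "SE", "SW"))) / max(nrow(it), 1L)
  rng_x <- range(c(it$halys, 0))
  rng_y <- range(c(it$net_cost, 0))
  lab <- tibble::tibble(
    quadrant = c("NE", "NW", "SE", "SW"),
    x = c(rng_x[2], rng_x[1], rng_x[2], rng_x[1]),
    y = c(rng_y[2], rng_y[2], rng_y[1], rng_y[1]),
    text = sprintf("%s %.0f%%", c("NE", "NW", "SE", "SW"), 100 * as.numeric(shares))
  )
  ggplot2::ggplot(it, ggplot2::aes(x = .data$halys, y = .data$net_cost / 1e6)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = wtp / 1e6, intercept = 0,
                         linetype = "dashed", colour = "grey30") +
    ggplot2::geom_point(alpha = 0.4, colour = "#2c7fb8") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y / 1e6,
                                    label = .data$text),
                       inherit.aes = FALSE, size = 3, colour = "grey30") +
    ggplot2::labs(
      x = "Incremental HALYs",
      y = "Incremental net cost (A$ millions)",
      title = "Cost-effectiveness plane",
      subtitle = sprintf("Dashed line: willingness-to-pay A$%s per HALY",
                         format(wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ce_plane
#' @param object A `fopl_psa` object.
#' @param ... Passed on (unused).
#' @method autoplot fopl_psa
#' @export
autoplot.fopl_psa <- function(object, wtp = NULL, ...) {
  plot_ce_plane(object, wtp = wtp)
}

#' Plot per-category attributable reformulation effects
#'
#' Horizontal bar chart of the percentage-point energy-density change
#' attributable to labelling, per category.
#'
#' @param object A `fopl_category_effects` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fopl_category_effects
#' @export
autoplot.fopl_category_effects <- function(object, ...) {
  dat <- object[is.finite(object$pct_attributable), ]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$pct_attributable,
    y = stats::reorder(.data$category, .data$pct_attributable)
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = "% change in energy density attributable to labelling (pp)",
      y = NULL,
      title = "Label-attributable reformulation by food category"
    ) +
    ggplot2::theme_minimal()
}
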