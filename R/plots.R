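#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination biplot
#'
#' Scatter of samples on the first two principal coordinates, optionally
#' overlaid with envfit vectors scaled by `sqrt(r2)` (the usual biplot
#' convention, so arrow length reflects how much community variation the
#' baseline factor explains).
#'
#' @param object an `fmt_pcoa` object.
#' @param envfit optional `fmt_envfit` tibble from [fit_env_vectors()].
#' @param colour optional named vector (by sample id) used to colour points,
#'   e.g. response labels.
#' @param arrow_scale multiplier on the arrow lengths.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fmt_pcoa
#' @export
autoplot.fmt_pcoa <- function(object, envfit = NULL, colour = NULL,
                              arrow_scale = NULL, ...) {
  sc <- tidy(object)
  pe <- object$proportion_explained
  if (!is.null(colour)) sc$group <- colour[sc$sample_id]
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PCo1, .data$PCo2)) +
    (if (is.null(colour)) ggplot2::geom_point() else
      ggplot2::geom_point(ggplot2::aes(colour = .data$group))) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * pe[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * pe[2])) +
    ggplot2::theme_minimal()
  if (!is.null(envfit)) {
    if (is.null(arrow_scale)) {
      arrow_scale <- 0.8 * max(abs(sc$PCo1), abs(sc$PCo2))
    }
    arr <- dplyr::filter(envfit, !.data$flagged) |>
      dplyr::mutate(x = .data$axis_1 * sqrt(.data$r2) * arrow_scale,
                    y = .data$axis_2 * sqrt(.data$r2) * arrow_scale)
    p <- p +
      ggplot2::geom_segment(
        data = arr, ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        inherit.aes = FALSE) +
      ggplot2::geom_text(
        data = arr, ggplot2::aes(.data$x * 1.08, .data$y * 1.08,
                                 label = .data$variable),
        size = 3, inherit.aes = FALSE)
  }
  p
}

#' Importance ranking plot for the response model
#'
#' Horizontal bars of the replicate-averaged Gini importances of the top
#' predictive features.
#'
#' @param object an `fmt_rfc` object.
#' @param k number of features shown.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fmt_rfc
#' @export
autoplot.fmt_rfc <- function(object, k = 10, ...) {
  imp <- utils::head(object$importance, k)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$importance_gini,
    y = stats::reorder(.data$feature, .data$importance_gini))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean decrease in Gini impurity (100-replicate mean)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Engraftment-rate time courses by response group
#'
#' Line chart of per-ASV engraftment rates over the post-FMT visits,
#' responders vs non-responders, for a chosen set of ASVs (default: the
#' ASVs selected by [differential_engrafters()], if `rates` carries them).
#'
#' @param rates tibble from [engraftment_rates()].
#' @param asvs character vector of ASV ids to show (default all).
#' @return A ggplot object.
#' @export
plot_engraftment_rates <- function(rates, asvs = NULL) {
  if (!is.null(asvs)) rates <- dplyr::filter(rates, .data$asv_id %in% asvs)
  ggplot2::ggplot(rates, ggplot2::aes(.data$timepoint_weeks, .data$rate,
                                      colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~asv_id) +
    ggplot2::scale_x_continuous(breaks = unique(rates$timepoint_weeks)) +
    ggplot2::labs(x = "weeks post-FMT", y = "engraftment rate") +
    ggplot2::theme_minimal()
}
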