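#' Mean-Fano factor plot with the theoretical curve family
#'
#' Scatter of per-gene (mean, Fano factor) points over the weakly
#' expressed window, with the theoretical curves for the requested
#' indices overlaid. Genes whose counts exceed 2 are drawn with a
#' distinct shape; they still fall on the curve of their effective
#' index.
#'
#' @param x a [count_matrix()] (or coercible).
#' @param k_list curve indices to overlay (default 0:2).
#' @param mean_max analysis window (default 1).
#' @return A ggplot object.
#' @export
plot_mean_fano <- function(x, k_list = 0:2, mean_max = 1) {
  x <- as_count_matrix(x)
  genes <- assign_curves(x, mean_max = mean_max)
  curves <- curve_samples(n_cells(x), k_list = k_list, mean_max = mean_max)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(.data$mean, .data$fano, group = .data$k),
      colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_point(
      data = genes,
      ggplot2::aes(.data$mean, .data$fano, colour = factor(.data$k),
                   shape = .data$simple),
      size = 1.4, alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "mean transcript count", y = "Fano factor",
                  colour = "curve k",
                  title = sprintf("mean-Fano factor plot (n_c = %d)", n_cells(x)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn match_lattice predicted lattice (open circles) with
#'   realized points filled, the standard overlay for judging which
#'   predicted points the data realize.
#' @param object a `lattice_match` object.
#' @param ... unused.
#' @method autoplot lattice_match
#' @export
autoplot.lattice_match <- function(object, ...) {
  pred <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(object$matched, "mean", "fano", "k"),
                  status = "observed"),
    dplyr::mutate(dplyr::select(object$missing, "mean", "fano", "k"),
                  status = "missing"))
  ggplot2::ggplot(pred, ggplot2::aes(.data$mean, .data$fano)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$status == "missing"),
                        shape = 1, colour = "steelblue", size = 2) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$status == "observed"),
                        shape = 16, colour = "navy", size = 1.3) +
    ggplot2::labs(x = "mean transcript count", y = "Fano factor",
                  title = sprintf(
                    "predicted lattice vs data (n_c = %d, k <= %d)",
                    object$n_c, object$k_max))
}

#' @describeIn delta_y histogram of spacing steps (in 1/n_c units) per
#'   curve; quantization means every bar sits on an integer.
#' @param object a `deltay_report`.
#' @param ... unused.
#' @method autoplot deltay_report
#' @export
autoplot.deltay_report <- function(object, ...) {
  steps <- tidyr::unnest(object[, c("k", "steps")], "steps")
  ggplot2::ggplot(steps, ggplot2::aes(factor(.data$steps))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(Delta * y ~ "in units of" ~ 1 / n[c]),
                  y = "number of successive-point spacings")
}
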