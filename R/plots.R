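#' Volcano plot of a Rank Product fit
#'
#' Log2 fold change against the significance of the better orientation
#' (-log10 of the smaller q-value), colored by the DEG call.
#'
#' @param object An `rp_dea` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rp_dea <- function(object, ...) {
  tab <- dplyr::mutate(object$table, q = pmin(.data$q_up, .data$q_down))
  ggplot2::ggplot(tab, ggplot2::aes(.data$log2fc, -log10(.data$q),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60",
                                            ns = "grey70")) +
    ggplot2::labs(
      title = sprintf("%s: %s vs %s", object$dataset_id,
                      object$contrast[1], object$contrast[2]),
      x = "log2 fold change", y = "-log10 q", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Bubble plot of enrichment results
#'
#' Shows the top terms by q-value: overlap ratio against term, sized by
#' overlap count and colored by -log10 q, faceted by namespace.
#'
#' @param object An `ora_result`.
#' @param top Number of terms per namespace.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ora_result <- function(object, top = 10, ...) {
  tab <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$namespace) |>
    dplyr::slice_min(.data$q, n = top, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(ratio = .data$k / .data$K,
                  term = stats::reorder(.data$term, -.data$q))
  ggplot2::ggplot(tab, ggplot2::aes(.data$ratio, .data$term,
                                    size = .data$k, colour = -log10(.data$q))) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$namespace),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "overlap / term size", y = NULL,
                  size = "overlap", colour = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Category bar chart of a specificity partition
#'
#' @param object A `specificity_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.specificity_partition <- function(object, ...) {
  tab <- tibble::as_tibble(object) |>
    dplyr::count(.data$category, .data$rrms_direction)
  ggplot2::ggplot(tab, ggplot2::aes(.data$category, .data$n,
                                    fill = .data$rrms_direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#27ae60",
                                          none = "grey70")) +
    ggplot2::labs(x = NULL, y = "genes", fill = "RRMS direction") +
    ggplot2::theme_minimal()
}
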