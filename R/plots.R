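# ggplot2 displays for the main result types.

#' Plot a quadripartite partition as a linear map
#'
#' @param partition partition tibble.
#' @return a ggplot object.
#' @export
plot_partition <- function(partition) {
  ggplot2::ggplot(partition) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$start + .data$length,
                   ymin = 0, ymax = 1, fill = .data$region)
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "region") +
    ggplot2::theme_minimal()
}

#' Plot RSCU values per codon, grouped by amino acid
#'
#' @param usage a [codon_usage_table()] tibble.
#' @return a ggplot object.
#' @export
plot_rscu <- function(usage) {
  ggplot2::ggplot(usage,
                  ggplot2::aes(x = .data$codon, y = .data$rscu)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~amino_acid, scales = "free_x") +
    ggplot2::labs(y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.nupt_profile
#' @export
plot_insertion_profile <- function(x) autoplot.nupt_profile(x)

#' Plot a per-base insertion profile
#'
#' Displays the full-genome projection (IR values halved and mirrored onto
#' both copies).
#'
#' @param object an `nupt_profile` object.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot nupt_profile
#' @export
autoplot.nupt_profile <- function(object, ...) {
  ggplot2::ggplot(object$display, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "plastome position (bp)", y = "per-base insertion value") +
    ggplot2::theme_minimal()
}
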