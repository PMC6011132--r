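#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot SSR frequency tables
#'
#' Stacked bar chart of locus counts per repeat type, filled by
#' repeat-unit bin.
#'
#' @param object An `ssr_freq` object from [tabulate_frequencies()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ssr_freq <- function(object, ...) {
  long <- object$by_repeat_type |>
    tidyr::pivot_longer(dplyr::starts_with("rep_"), names_to = "bin",
                        values_to = "count") |>
    dplyr::mutate(bin = factor(sub("^rep_", "", .data$bin),
                               levels = bin_labels()),
                  repeat_type = factor(.data$repeat_type,
                                       levels = repeat_type_names()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$repeat_type,
                                     y = .data$count,
                                     fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "SSR loci", fill = "Repeat units") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot marker-panel heterozygosity
#'
#' Observed versus expected heterozygosity per locus, one panel per
#' population; points above the diagonal have an excess of heterozygotes.
#'
#' @param object An `ssr_panel` object from [summarize_panel()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ssr_panel <- function(object, ...) {
  ggplot2::ggplot(object$summaries,
                  ggplot2::aes(x = .data$he, y = .data$ho,
                               label = .data$locus)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pop)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Expected heterozygosity (He)",
                  y = "Observed heterozygosity (Ho)") +
    ggplot2::theme_minimal()
}
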