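#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Enrichment along the genome
#'
#' The screen's signature panel: per-spacer enrichment against protospacer
#' position, one facet per strand, with operon spans shaded. Spacers
#' matching the mRNA (plus) strand should sit near the no-selection line;
#' targeting (minus-strand) spacers rise wherever their transcript is made
#' early enough to matter.
#'
#' @param enr Annotated enrichment table (needs `midpoint`, `strand`,
#'   `enrichment`).
#' @param genome Optional [genome_annotation()] whose operons are shaded.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_enrichment_map <- function(enr, genome = NULL, alpha = 0.4) {
  d <- enr |>
    filter(!is.na(.data$enrichment), !is.na(.data$midpoint)) |>
    mutate(strand = factor(.data$strand, c("+", "-"),
                           c("plus strand", "minus strand")))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$midpoint, .data$enrichment))
  if (!is.null(genome) && nrow(genome$operons) > 0) {
    p <- p + ggplot2::geom_rect(
      data = genome$operons,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$name),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_point(size = 0.4, alpha = alpha) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "protospacer midpoint (nt)", y = "enrichment (f_post / f_t0)",
                  fill = "operon") +
    ggplot2::theme_minimal()
}

#' @rdname plot_enrichment_map
#' @param object An `enrichment_table`.
#' @param ... Passed to [plot_enrichment_map()].
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  plot_enrichment_map(object, ...)
}

#' Acquisition RPM tracks
#'
#' Strand-separated single-nucleotide RPM coverage per replicon (minus
#' strand drawn downward).
#'
#' @param object An `acquisition_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acquisition_profile
#' @export
autoplot.acquisition_profile <- function(object, ...) {
  d <- object$rpm |>
    mutate(signed_rpm = if_else(.data$strand == "+", .data$rpm, -.data$rpm))
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$signed_rpm,
                                  colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(~replicon, ncol = 1, scales = "free") +
    ggplot2::labs(x = "position (nt)", y = "RPM (minus strand downward)") +
    ggplot2::theme_minimal()
}

#' Time-course coverage tracks
#'
#' Normalized (or raw) coverage along the replicon, one panel per
#' timepoint; the stepped early/late structure of phage transcription shows
#' as regions switching on between panels.
#'
#' @param object A `coverage_profile`.
#' @param smoothing_window Running-mean window for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, smoothing_window = 201L, ...) {
  value <- if ("norm" %in% names(object)) "norm" else "count"
  d <- object |>
    group_by(.data$timepoint, .data$strand) |>
    arrange(.data$position, .by_group = TRUE) |>
    mutate(smoothed = running_mean(.data[[value]], smoothing_window)) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$smoothed,
                                  colour = .data$strand)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~timepoint, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position (nt)",
                  y = sprintf("%s coverage (window %d)", value, smoothing_window)) +
    ggplot2::theme_minimal()
}

#' Group enrichment summary plot
#'
#' Mean +/- SD per region x strand group.
#'
#' @param summary Output of [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "mean enrichment ± SD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
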