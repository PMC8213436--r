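# ggplot2 views of the main result types.

#' Volcano plot of a differential-expression table
#'
#' @param object A `deg_table` from [call_degs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  d <- tidy.deg_table(object)
  d$status <- ifelse(!d$flagged, "not significant", d$direction)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "lfc_cutoff"),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "p_cutoff")),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c23b22", down = "#1f6fb2",
                                            "not significant" = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = attr(object, "contrast"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stage summary plot of a two-stage hub extraction
#'
#' Node counts and densities per stage: hub screening should shrink the
#' network while concentrating it.
#'
#' @param object A `hub_result` from [extract_hubs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hub_result
#' @export
autoplot.hub_result <- function(object, ...) {
  s <- object$stages
  d <- tibble::tibble(
    stage = factor(c(s$stage, max(s$stage) + 1L),
                   labels = c(sprintf("stage %d", s$stage), "hubs")),
    nodes = c(s$nodes, length(object$hubs)),
    density = c(s$density, NA)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$nodes)) +
    ggplot2::geom_col(fill = "#5b8fa8") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$density), as.character(.data$nodes),
                     sprintf("%d nodes\ndensity %.3f", .data$nodes,
                             .data$density))),
      vjust = -0.2, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(x = NULL, y = "nodes",
                  title = "Median-threshold hub extraction") +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' @param object An `enrichment_table` from [enrich()].
#' @param top Number of top sets to show (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, top = 30, ...) {
  d <- utils::head(tidy.enrichment_table(object), top)
  d$set <- factor(d$set, levels = rev(d$set))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$q_value), y = .data$set,
                                  size = .data$overlap)) +
    ggplot2::geom_point(colour = "#7b5aa6") +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "-log10 q", y = NULL, size = "overlap",
                  title = "Gene-set over-representation") +
    ggplot2::theme_minimal()
}
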