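# ggplot2 views of the main result types.

CATEGORY_COLORS <- c(native_mito = "grey70", native_MTPT = "#66c2a5",
                     foreign_MTPT = "#fc8d62", foreign_mito = "#8da0cb",
                     unclassified = "grey90")

#' Genome map of window classifications and foreign segments
#'
#' @param object A classified window tibble from [classify_windows()].
#' @param segments Optional segment tibble drawn as a track above.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hgt_windows <- function(object, segments = NULL, ...) {
  p <- ggplot2::ggplot(object) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = 1, fill = .data$category)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$seq_id)) +
    ggplot2::scale_fill_manual(values = CATEGORY_COLORS) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(segments) && nrow(segments) > 0)
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 1.1,
                   ymax = 1.4, fill = .data$category))
  p
}

#' Plot a genome's classification map
#'
#' Convenience wrapper: classifies nothing, just draws a window
#' classification tibble (optionally with merged segments).
#'
#' @param windows Tibble from [classify_windows()].
#' @param segments Optional tibble from [merge_segments()].
#' @return A ggplot.
#' @export
plot_genome_map <- function(windows, segments = NULL) {
  class(windows) <- c("hgt_windows", class(windows))
  autoplot(windows, segments = segments)
}

#' @describeIn editing_state_matrix Tile view of the editing-state matrix
#'   (C/T/other/gap per taxon and conserved site).
#' @param object An `hgt_editing_matrix`.
#' @param ... Unused.
#' @export
autoplot.hgt_editing_matrix <- function(object, ...) {
  df <- as.data.frame.table(unclass(object), stringsAsFactors = FALSE)
  names(df) <- c("taxon", "column", "state")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$taxon,
                                   fill = .data$state)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(C = "#4575b4", T = "#d73027",
                                          other = "grey60", gap = "grey90")) +
    ggplot2::labs(x = "conserved editing site (alignment column)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn shared_foreign_venn Bar view of the Venn region base counts,
#'   one bar per region and coordinate frame.
#' @param object An `hgt_venn`.
#' @param ... Unused.
#' @export
autoplot.hgt_venn <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$bp,
                                       fill = .data$frame)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "shared foreign sequence (bp)",
                  fill = "counted in") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Expression contrast plot
#'
#' Log-scale TPM by origin class.
#'
#' @param expression Tibble with `origin` and `tpm` (from
#'   [expression_contrast()] or [compute_tpm()]).
#' @return A ggplot.
#' @export
plot_expression <- function(expression) {
  ggplot2::ggplot(expression, ggplot2::aes(x = .data$origin, y = .data$tpm,
                                           color = .data$origin)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "TPM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
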