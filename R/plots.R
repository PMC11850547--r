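#' Forest plot of paired logFC estimates with confidence intervals
#'
#' One point per taxon at the bias-corrected logFC, error bars at the
#' confidence bounds, colored by sign, significance indicated by shape --
#' the standard presentation of paired-habitat profiles.
#'
#' @param object A `microref_da`.
#' @param top Show only the `top` taxa by |logFC| (NULL for all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microref_da <- function(object, top = 30, ...) {
  r <- tidy(object)
  if (!is.null(top)) r <- dplyr::slice_max(r, abs(.data$logfc), n = top)
  r <- dplyr::mutate(r, taxon = stats::reorder(.data$taxon, .data$logfc),
                     direction = ifelse(.data$logfc >= 0, "up in A", "up in B"))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$logfc, y = .data$taxon,
                                  color = .data$direction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2) +
    ggplot2::scale_color_manual(values = c("up in A" = "#c0392b",
                                           "up in B" = "#2980b9")) +
    ggplot2::labs(x = "logFC (natural log, A vs B)", y = NULL,
                  shape = "FDR < 0.05", color = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of in-range proportions from a screening report
#'
#' @param object A `microref_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microref_screen <- function(object, ...) {
  r <- dplyr::arrange(tidy(object), .data$prop_within)
  r$taxon <- factor(r$taxon, levels = r$taxon)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$prop_within, y = .data$taxon,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    ggplot2::labs(x = "proportion of screened subjects within reference range",
                  y = NULL, fill = "selected") +
    ggplot2::theme_minimal()
}

#' PC1-PC2 scatter of logFC profiles colored by group
#'
#' @param object A `microref_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microref_pca <- function(object, ...) {
  s <- tidy(object)
  ve <- object$var_explained
  ggplot2::ggplot(s, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  color = .data$group)) +
    ggplot2::geom_point(size = 2.5, alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.9, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of alpha-diversity reference intervals
#'
#' @param intervals Tibble with columns habitat (or any grouping), measure,
#'   lower, upper -- e.g. stacked [alpha_reference_interval()] rows.
#' @return A ggplot.
#' @export
plot_reference_intervals <- function(intervals) {
  ggplot2::ggplot(intervals,
                  ggplot2::aes(x = .data$habitat, ymin = .data$lower,
                               ymax = .data$upper)) +
    ggplot2::geom_errorbar(width = 0.3, linewidth = 0.9, color = "#2c3e50") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "reference interval (central 95%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
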