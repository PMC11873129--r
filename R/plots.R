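# Minimal figure helpers (ggplot2 is suggested, not required).

#' Dot plot of module-trait association strength
#'
#' One point per module x trait at -log10(p), sized by |coefficient|,
#' with the 0.05 and Bonferroni reference lines.
#'
#' @param assoc result of [module_trait_correlations()].
#' @param file optional SVG path; when `NULL` the ggplot object is
#'   returned.
#' @return a ggplot object, invisibly when written to file.
#' @export
plot_module_trait_dotplot <- function(assoc, file = NULL) {
  stop_if_not(requireNamespace("ggplot2", quietly = TRUE),
              "ggplot2 is required for plotting")
  assoc$logp <- -log10(assoc$p)
  gg <- ggplot2::ggplot(assoc,
                        ggplot2::aes(x = .data$logp, y = .data$trait,
                                     size = abs(.data$coefficient),
                                     colour = .data$trait)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = -log10(assoc$bonferroni_threshold[1]),
                        linetype = "dashed", colour = "black") +
    ggplot2::labs(x = "-log10(p)", y = NULL,
                  size = "|coefficient|") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (is.null(file)) return(gg)
  grDevices::svg(file, width = 7, height = 4)
  print(gg); grDevices::dev.off()
  invisible(gg)
}

#' Bar plot of cell-type enrichment
#'
#' Standard deviations from the bootstrap mean per cell type, starred at
#' q < 0.05.
#'
#' @param ewce result of [ewce_bootstrap()].
#' @param file optional SVG path.
#' @return a ggplot object, invisibly when written to file.
#' @export
plot_ewce_bars <- function(ewce, file = NULL) {
  stop_if_not(requireNamespace("ggplot2", quietly = TRUE),
              "ggplot2 is required for plotting")
  ewce$star <- ifelse(ewce$q < 0.05, "*", "")
  gg <- ggplot2::ggplot(ewce,
                        ggplot2::aes(x = .data$celltype,
                                     y = .data$sd_from_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), vjust = 0) +
    ggplot2::labs(x = NULL, y = "SD from bootstrap mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (is.null(file)) return(gg)
  grDevices::svg(file, width = 6, height = 4)
  print(gg); grDevices::dev.off()
  invisible(gg)
}
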