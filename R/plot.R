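# Heatmap display of condition-contrast matrices: increases in green,
# decreases in red, not-applicable cells in grey.

#' Heatmap of a condition-contrast delta matrix
#'
#' Displays per-organism composition changes with the conventional
#' colour-coding of membrane-adaptation heatmaps: green for acids that
#' increased under the first contrast condition, red for decreases, grey
#' for acids that were censored or undetected in both conditions.
#'
#' @param m A `delta_matrix` from [delta_matrix()] (raw or normalized).
#' @return A ggplot object.
#' @export
plot_delta_heatmap <- function(m) {
  stopifnot(inherits(m, "delta_matrix"))
  long <- delta_to_long(m)
  long$fatty_acid <- factor(long$fatty_acid, levels = colnames(m))
  long$organism <- factor(long$organism, levels = rev(rownames(m)))
  ct <- attr(m, "contrast")
  fill_lab <- if (isTRUE(attr(m, "normalized"))) {
    "normalized\ndelta"
  } else {
    "delta\n(% points)"
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fatty_acid,
                                     y = .data$organism,
                                     fill = .data$delta)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "firebrick3", mid = "white",
                                  high = "green4", midpoint = 0,
                                  na.value = "grey80", name = fill_lab) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(ct[1], " vs ", ct[2])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
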