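#' Plot a chromatin metaprofile
#'
#' @param object A `bdp_profile`.
#' @param ... Unused.
#' @return A ggplot: normalized reads count against position.
#' @export
autoplot.bdp_profile <- function(object, ...) {
  xlab <- if (identical(attr(object, "orientation"), "pair"))
    "Position relative to BDP (bp; + = downstream of higher-FPKM gene)"
  else "Position relative to TSS (bp)"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$window_center, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = xlab,
                  y = "Normalized reads (per bp per million mapped)",
                  title = attr(object, "mark")) +
    ggplot2::theme_minimal()
}

#' Plot coexpressed fraction against TSS distance
#'
#' @param dist_table Output of [coexpression_by_distance()].
#' @return A ggplot.
#' @export
plot_coexpression_distance <- function(dist_table) {
  ggplot2::ggplot(dist_table,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$coexpressed_frac)) +
    ggplot2::geom_col(width = (dist_table$bin_end - dist_table$bin_start)[1] * 0.9) +
    ggplot2::labs(x = "TSS distance (bp)", y = "Coexpressed fraction") +
    ggplot2::theme_minimal()
}

#' Compare promoter GC between groups
#'
#' @param features Tibble with `gc` and a `group` column (e.g. BDP type vs
#'   random UDP controls), as built from [promoter_features()].
#' @return A ggplot boxplot.
#' @export
plot_gc_comparison <- function(features) {
  ggplot2::ggplot(features, ggplot2::aes(x = .data$group, y = .data$gc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Promoter GC fraction") +
    ggplot2::theme_minimal()
}

#' Plot motif enrichment
#'
#' @param object A `bdp_enrichment`.
#' @param ... Unused.
#' @return A ggplot of Z against motif, coloured by significance.
#' @export
autoplot.bdp_enrichment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$name, .data$z),
                                   y = .data$z, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Overrepresentation Z") +
    ggplot2::theme_minimal()
}
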