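#' Plot a replication timing profile
#'
#' Raw per-bin scores as points and the loess-smoothed curve as a line,
#' one panel per chromosome. High values replicate early.
#'
#' @param profile a [timing_score()]/[smooth_profile()] table.
#' @param chroms optional chromosomes to show.
#' @return a ggplot.
#' @export
plot_timing_profile <- function(profile, chroms = NULL) {
  if (!is.null(chroms)) profile <- profile[profile$chrom %in% chroms, ]
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$score), size = 0.3,
                        alpha = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "replication timing score") +
    ggplot2::ylim(0.1, 0.9) +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                colour = "firebrick", na.rm = TRUE)
  }
  p
}

domain_fill <- c(early = "firebrick", late = "steelblue",
                 indeterminate = "grey80",
                 static_early = "firebrick", static_late = "steelblue",
                 dynamic = "grey40")

#' @describeIn segment_genome plot the domain intervals as coloured bars
#'   per chromosome (early red, late blue, indeterminate grey).
#' @param object,x a `repli_segmentation`.
#' @param ... unused.
#' @export
autoplot.repli_segmentation <- function(object, ...) {
  d <- object$domains
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start / 1e6,
                                    xmax = .data$end / 1e6,
                                    ymin = 0, ymax = 1,
                                    fill = .data$label)) +
    ggplot2::scale_fill_manual(values = domain_fill) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = paste("Replication domains:", object$sample)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @describeIn classify_positions plot per-class genome fractions as a
#'   bar chart.
#' @param object,x a `repli_classes`.
#' @param ... unused.
#' @export
autoplot.repli_classes <- function(object, ...) {
  f <- object$fractions
  ggplot2::ggplot(f, ggplot2::aes(x = .data$class, y = 100 * .data$fraction,
                                  fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = domain_fill) +
    ggplot2::labs(x = NULL, y = "% of genome") +
    ggplot2::theme_minimal()
}
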