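#' Violin plots of per-individual burden metrics
#'
#' One violin (with an inlaid box) per group for the burden score and the
#' carried-variant count — the standard way to show the group-level shift the
#' rank-sum tests assess.
#'
#' @param object A `burden_fit` from [burden_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_fit
#' @export
autoplot.burden_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profiles,
                              c("burden_score", "variant_count"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.6, colour = "grey30") +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4,
                          fill = "white") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.burden_fit
#' @export
plot_burden_profiles <- function(object, ...) autoplot.burden_fit(object, ...)

#' Per-gene association p-values
#'
#' Dot plot of -log10 empirical p-values (burden and C-alpha) for the powered
#' genes, with the adjusted Bonferroni threshold as a dashed line.
#'
#' @param object A `gene_assoc` from [gene_association()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_assoc
#' @export
autoplot.gene_assoc <- function(object, ...) {
  g <- object$genes
  if (!nrow(g)) abort("No genes to plot.")
  long <- tidyr::pivot_longer(g, c("p_burden", "p_calpha"),
                              names_to = "test", values_to = "p")
  alpha <- g$alpha_adjusted[1]
  pl <- ggplot2::ggplot(long,
                        ggplot2::aes(x = stats::reorder(.data$gene, -.data$p),
                                     y = -log10(.data$p),
                                     colour = .data$test,
                                     shape = .data$tested)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                  colour = NULL, shape = "powered (I < threshold)") +
    ggplot2::theme_minimal()
  if (!is.na(alpha)) {
    pl <- pl + ggplot2::geom_hline(yintercept = -log10(alpha),
                                   linetype = "dashed", colour = "grey40")
  }
  pl
}

#' Threshold-sweep variability curve
#'
#' Plots the coefficient of variation of per-individual burden scores against
#' the sequenced-fraction threshold grid, marking the argmin.
#'
#' @param sweep Tibble from [sweep_group_fraction_threshold()].
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$threshold,
                                      y = .data$variability)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_argmin), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "per-group sequenced-fraction threshold",
                  y = "CV of per-individual burden scores") +
    ggplot2::theme_minimal()
}
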