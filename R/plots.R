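#' Plot per-scaffold copy number
#'
#' One point per window, per sample, for the largest scaffolds — the view in
#' which collapsed within-GRC duplications stand out as elevated normalized
#' coverage.
#'
#' @param windows Window tibble from [copy_number_windows()].
#' @param n_scaffolds Show the longest `n_scaffolds` scaffolds.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(windows, n_scaffolds = 12L) {
  sizes <- windows %>%
    group_by(.data$scaffold) %>%
    summarise(bp = sum(.data$end - .data$start), .groups = "drop") %>%
    slice_max(.data$bp, n = n_scaffolds)
  d <- filter(windows, .data$scaffold %in% sizes$scaffold)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$scaffold, -(.data$end - .data$start), FUN = sum),
    y = .data$copy_number, colour = .data$sample)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 95, size = 8,
                          colour = "black") +
    ggplot2::labs(x = NULL, y = "normalized copy number", colour = "sample") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot expected vs observed A-chromosomal origin of GRC sequence
#'
#' @param origin Result of [origin_attribution()].
#' @return A ggplot object.
#' @export
plot_origin <- function(origin) {
  d <- tidyr::pivot_longer(origin$proportions, c("expected", "observed"),
                           names_to = "kind", values_to = "proportion")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chromosome, y = .data$proportion,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "A chromosome", y = "proportion of GRC sequence",
                  fill = NULL) +
    ggplot2::theme_bw()
}

#' Histogram of divergence polarity
#'
#' Difference in mismatch proportion of each GRC region against the two
#' species' A chromosomes; regions left of zero align better to species 1.
#'
#' @param polarity Tibble from [divergence_polarity()].
#' @param binwidth Histogram bin width on the mismatch-difference axis.
#' @return A ggplot object.
#' @export
plot_divergence <- function(polarity, binwidth = 0.002) {
  ggplot2::ggplot(polarity, ggplot2::aes(x = .data$d, fill = .data$d > 0)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "difference in mismatch proportion (sp1 - sp2)",
                  y = "regions") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the completeness-expression relationship
#'
#' @param object A `grc_expr_fit` from [completeness_expression_fit()].
#' @param ... Unused.
#' @return A ggplot object: log2(FPKM) against completeness with the OLS line.
#' @export
autoplot.grc_expr_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$completeness, y = log2(.data$fpkm))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "normalized completeness", y = "log2(FPKM)") +
    ggplot2::theme_bw()
}
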