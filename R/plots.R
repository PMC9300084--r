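#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline facet_wrap
#'   labs theme_minimal geom_boxplot geom_jitter coord_flip geom_hline
#' @export
ggplot2::autoplot

#' Scatter of paired facility scores
#'
#' One panel per quality measure, each facility's earlier-wave score against
#' its score two years later, with the identity line; tight diagonal clouds
#' indicate stable measures.
#'
#' @param object a `qualstab_stability` object.
#' @param alpha point transparency.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qualstab_stability <- function(object, alpha = 0.4, ...) {
  ggplot(object$paired, aes(x = .data$score_t0, y = .data$score_t1)) +
    geom_point(alpha = alpha, size = 0.8) +
    geom_abline(linetype = "dashed", colour = "grey40") +
    facet_wrap(~measure) +
    labs(x = "Score, first assessment", y = "Score, 2 years later") +
    theme_minimal()
}

#' Plot coverage differences between SPA references
#'
#' Distribution of the signed relative difference in adjusted coverage when
#' the quality input comes from assessments two years before the reference
#' period, by service and adjustment measure.
#'
#' @param differences output of [compare_adjusted_coverage()].
#' @param level which level's estimates to plot.
#' @return A ggplot object.
#' @export
plot_coverage_differences <- function(differences,
                                      level = c("major_region", "national")) {
  level <- match.arg(level)
  d <- differences[differences$level == level &
                     !is.na(differences$signed_relative_diff_pct), ]
  d$label <- paste(d$service, d$adjustment, sep = "\n")
  ggplot(d, aes(x = .data$label, y = .data$signed_relative_diff_pct)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 0.9) +
    coord_flip() +
    labs(x = NULL, y = "Relative difference in adjusted coverage (%)") +
    theme_minimal()
}
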