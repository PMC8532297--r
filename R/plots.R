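# ggplot2 views of the main result types. These emit plot-ready figures
# from the tables the analysis functions return; the tables themselves
# remain the primary interface.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   facet_wrap labs theme_minimal
NULL

#' Plot nucleotide composition summaries
#'
#' A+T content (or a skew) per group, faceted by partition.
#'
#' @param report tibble from [composition_report()].
#' @param metric column to plot (`"at_content"`, `"at_skew"`, `"gc_skew"`).
#' @param level `"sample"` or `"tribe"` rows.
#' @return a ggplot object.
#' @export
plot_composition <- function(report, metric = "at_content", level = "tribe") {
  dat <- report[report$level == level, ]
  ggplot(dat, aes(x = .data$group, y = .data[[metric]])) +
    geom_col(fill = "steelblue") +
    facet_wrap(~partition) +
    labs(x = NULL, y = metric) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot rank-stratified mean distances
#'
#' @param rank_tab tibble from [rank_mean_distances()] (one or several
#'   genes row-bound).
#' @return a ggplot object.
#' @export
plot_rank_distances <- function(rank_tab) {
  ggplot(rank_tab, aes(x = .data$rank_category, y = .data$mean_distance,
                       group = .data$gene, colour = .data$gene)) +
    geom_line() + geom_point() +
    labs(x = NULL, y = "mean K2P distance") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname sliding_pi
#' @param object a `diversity_profile`.
#' @param ... ignored.
#' @export
autoplot.diversity_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$midpoint, y = .data$pi, colour = .data$gene)) +
    geom_line() +
    labs(x = "window midpoint (usable site)", y = "nucleotide diversity") +
    theme_minimal()
}

#' @rdname pi_profile
#' @param object a `pi_profile` (profiles of several partitions can be
#'   row-bound first).
#' @param measure `"net"` or `"per_site"`.
#' @param ... ignored.
#' @export
autoplot.pi_profile <- function(object, measure = c("net", "per_site"), ...) {
  measure <- match.arg(measure)
  ggplot(object, aes(x = .data$time, y = .data[[measure]],
                     colour = .data$partition)) +
    geom_line() +
    labs(x = "time depth (root = 1)",
         y = sprintf("%s phylogenetic informativeness", measure)) +
    theme_minimal()
}
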