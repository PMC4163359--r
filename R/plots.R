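# ggplot2 views of the two result types.

#' Plot mean-across-sites versus pooled scores per measure
#'
#' The comparison view of the experiment grid: for each measure
#' configuration, the unweighted mean of the site-level balanced scores next
#' to the pooled (all-sites) score, faceted by task. The dashed line marks
#' chance (0.5).
#'
#' @param object A `conn_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conn_experiment <- function(object, ...) {
  comp <- mean_vs_pooled(object) |>
    dplyr::mutate(config = paste0(.data$measure, "\n", .data$graph_kind,
                                  ifelse(is.na(.data$cutoff), "",
                                         sprintf(" %.2f", .data$cutoff)))) |>
    tidyr::pivot_longer(c("mean_site_score", "pooled_score"),
                        names_to = "analysis", values_to = "score") |>
    dplyr::mutate(analysis = dplyr::recode(.data$analysis,
                                           mean_site_score = "mean across sites",
                                           pooled_score = "pooled"))
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$config, y = .data$score,
                                     fill = .data$analysis)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$task), ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "balanced score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a discriminative map's weight profile
#'
#' Absolute hyperplane coefficients over all nodes, with the selected top
#' fraction highlighted.
#'
#' @param object A `discriminative_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discriminative_map <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi, y = .data$abs_weight,
                                  fill = .data$selected)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               labels = c("other", "selected")) +
    ggplot2::labs(x = "ROI index", y = "|hyperplane coefficient|",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
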