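# broom-style tidiers for the fitted objects.

#' Tidy a classification result into per-fold predictions
#'
#' @param x A `classification_result`.
#' @param ... Unused.
#' @return Tibble with one row per subject: `subject_id`, `actual`,
#'   `predicted`, `correct`.
#' @export
tidy.classification_result <- function(x, ...) {
  tibble(subject_id = x$subject_id,
         actual = as.character(x$actual),
         predicted = as.character(x$predicted),
         correct = x$actual == x$predicted)
}

#' One-row summary of a classification result
#'
#' @param x A `classification_result`.
#' @param ... Unused.
#' @return One-row tibble: task, scope, feature configuration, class sizes,
#'   sensitivity, specificity, balanced score and its integer-percent form.
#' @export
glance.classification_result <- function(x, ...) {
  tibble(task = x$task, scope = x$scope, measure = x$measure,
         graph_kind = x$graph_kind, cutoff = x$cutoff,
         n_pos = x$n_pos, n_neg = x$n_neg,
         sensitivity = x$sensitivity, specificity = x$specificity,
         score = x$score, percent = report_percent(x$score))
}

#' Tidy a discriminative map
#'
#' @param x A `discriminative_map`.
#' @param ... Unused.
#' @return Tibble over all nodes: `roi`, `weight`, `abs_weight`, `rank`
#'   (position in the magnitude ordering) and `selected`.
#' @export
tidy.discriminative_map <- function(x, ...) {
  rank <- integer(length(x$weights))
  rank[x$ranking] <- seq_along(x$ranking)
  tibble(roi = x$roi, weight = x$weights, abs_weight = abs(x$weights),
         rank = rank, selected = rank <= x$k)
}

#' Results grid of an experiment
#'
#' @param x A `conn_experiment`.
#' @param ... Unused.
#' @return The long results tibble (one row per grid cell, skips included).
#' @export
tidy.conn_experiment <- function(x, ...) {
  x$results
}

#' One-row summary of an experiment
#'
#' @param x A `conn_experiment`.
#' @param ... Unused.
#' @return One-row tibble with cohort and grid sizes and the best
#'   non-skipped cell.
#' @export
glance.conn_experiment <- function(x, ...) {
  ok <- dplyr::filter(x$results, !.data$skipped)
  best <- if (nrow(ok)) ok[which.max(ok$score), ] else NULL
  tibble(n_subjects = nrow(x$cohort_info),
         n_sites = dplyr::n_distinct(x$cohort_info$site),
         n_cells = nrow(x$results),
         n_skipped = sum(x$results$skipped),
         best_score = if (is.null(best)) NA_real_ else best$score,
         best_measure = if (is.null(best)) NA_character_ else
           paste0(best$measure, "/", best$graph_kind,
                  ifelse(is.na(best$cutoff), "", sprintf("@%.2f", best$cutoff))))
}
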