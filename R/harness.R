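# Experiment orchestration: tasks x measures x graph kinds x cut-offs x
# (site-by-site, pooled), from one config, with centralities computed once
# per subject and shared across every cell.

#' Configure a full classification experiment
#'
#' @param cohort Either a [cohort_spec()] (simulated on demand) or a path to
#'   a cohort manifest CSV ([read_cohort()]).
#' @param cutoffs Binarization cut-offs, each in (0, 1).
#' @param measures Centrality battery (see [centrality_profile()]).
#' @param tasks Subset of `c("control_vs_adhd", "inattentive_vs_combined")`.
#' @param scopes Scopes to evaluate; `NULL` means every site plus `"all"`
#'   (the pooled concatenation).
#' @param cost SVM regularization constant.
#' @param map_score_gate Minimum balanced score for a grid cell to receive a
#'   discriminative map in [make_maps()].
#' @param top_fraction Fraction of nodes per discriminative map.
#' @param out_dir Optional directory for results CSV and run log.
#' @param seed Optional integer; when `cohort` is a spec, overrides its seed.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(cohort,
                              cutoffs = c(0.1, 0.15, 0.25),
                              measures = weighted_measures,
                              tasks = c("control_vs_adhd", "inattentive_vs_combined"),
                              scopes = NULL,
                              cost = 1,
                              map_score_gate = 0.70,
                              top_fraction = 0.05,
                              out_dir = NULL,
                              seed = NULL) {
  if (any(cutoffs <= 0 | cutoffs >= 1)) abort("cutoffs must lie in (0, 1)")
  if (top_fraction <= 0 || top_fraction > 1) abort("`top_fraction` must lie in (0, 1]")
  for (task in tasks) task_groups(task)
  structure(
    list(cohort = cohort, cutoffs = cutoffs, measures = measures,
         tasks = tasks, scopes = scopes, cost = cost,
         map_score_gate = map_score_gate, top_fraction = top_fraction,
         out_dir = out_dir, seed = seed),
    class = "experiment_config"
  )
}

# the 14-row default battery: 5 weighted + 3 unweighted x |cutoffs|
measure_grid <- function(measures, cutoffs) {
  dplyr::bind_rows(
    tibble(measure = intersect(measures, weighted_measures),
           graph_kind = "weighted", cutoff = NA_real_),
    tidyr::expand_grid(measure = intersect(measures, unweighted_measures),
                       cutoff = cutoffs) |>
      dplyr::mutate(graph_kind = "unweighted", .after = "measure")
  )
}

#' Run the full experiment grid
#'
#' Resolves the cohort, computes the centrality battery once per subject,
#' then evaluates leave-one-subject-out classification for every (task,
#' measure configuration, scope) cell. Infeasible cells (a class with fewer
#' than two subjects in scope) are recorded as explicit skips, not dropped,
#' so the grid is always complete and auditable. Deterministic given the
#' config.
#'
#' @param config An [experiment_config()].
#' @return A `conn_experiment` object holding the results grid (`$results`,
#'   also via [tidy()]), the cached centrality table (`$centralities`), and
#'   the config. If `config$out_dir` is set, writes `results.csv` and
#'   `run_log.txt` (config hash, sizes, timings).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  cohort <- resolve_cohort(config)
  centralities <- compute_centralities(cohort, config$cutoffs, config$measures)
  scopes <- config$scopes %||% c(sort(unique(cohort$site)), "all")
  grid <- tidyr::expand_grid(task = config$tasks,
                             measure_grid(config$measures, config$cutoffs),
                             scope = scopes)
  rows <- purrr::pmap(grid, function(task, measure, graph_kind, cutoff, scope) {
    res <- tryCatch(
      loocv_classify(
        build_feature_table(centralities, measure, graph_kind,
                            cutoff = if (is.na(cutoff)) NULL else cutoff,
                            task = task, scope = scope),
        cost = config$cost),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      tibble(task, measure, graph_kind, cutoff, scope,
             n_pos = NA_integer_, n_neg = NA_integer_,
             sensitivity = NA_real_, specificity = NA_real_, score = NA_real_,
             skipped = TRUE, skip_reason = res)
    } else {
      tibble(task, measure, graph_kind, cutoff, scope,
             n_pos = res$n_pos, n_neg = res$n_neg,
             sensitivity = res$sensitivity, specificity = res$specificity,
             score = res$score, skipped = FALSE, skip_reason = NA_character_)
    }
  })
  results <- dplyr::bind_rows(rows)
  out <- structure(
    list(results = results, centralities = centralities,
         cohort_info = dplyr::select(cohort, -"timeseries"), config = config),
    class = "conn_experiment"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(config$out_dir, "results.csv"), row.names = FALSE)
    writeLines(c(
      sprintf("centconn %s", as.character(utils::packageVersion("centconn"))),
      sprintf("config hash: %s", rlang::hash(config)),
      sprintf("subjects: %d  rois: %d", nrow(cohort),
              ncol(cohort$timeseries[[1]])),
      sprintf("grid cells: %d (skipped %d)", nrow(results), sum(results$skipped)),
      sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    ), file.path(config$out_dir, "run_log.txt"))
  }
  out
}

resolve_cohort <- function(config) {
  if (inherits(config$cohort, "cohort_spec")) {
    spec <- config$cohort
    if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
    simulate_cohort(spec)
  } else if (is.character(config$cohort)) {
    read_cohort(config$cohort)
  } else if (is.data.frame(config$cohort)) {
    config$cohort
  } else {
    abort("`cohort` must be a cohort_spec, a manifest path, or a cohort tibble")
  }
}

#' @export
print.conn_experiment <- function(x, ...) {
  cat(sprintf("<conn_experiment> %d grid cells (%d skipped), %d subjects\n",
              nrow(x$results), sum(x$results$skipped),
              nrow(x$cohort_info)))
  invisible(x)
}

#' Compare mean-across-sites with pooled classification scores
#'
#' For each (task, measure configuration) with a pooled (`"all"`-scope)
#' record, reports the unweighted mean of the site-level scores next to the
#' pooled score and their difference.
#'
#' @param x A `conn_experiment` or its results tibble.
#' @return Tibble with `mean_site_score`, `pooled_score`, `difference`
#'   (mean minus pooled) and `n_sites` (sites contributing to the mean).
#' @export
mean_vs_pooled <- function(x) {
  results <- if (inherits(x, "conn_experiment")) x$results else x
  ok <- dplyr::filter(results, !.data$skipped)
  site_part <- ok |>
    dplyr::filter(.data$scope != "all") |>
    dplyr::summarise(mean_site_score = mean(.data$score),
                     n_sites = dplyr::n(),
                     .by = c("task", "measure", "graph_kind", "cutoff"))
  pooled_part <- ok |>
    dplyr::filter(.data$scope == "all") |>
    dplyr::select("task", "measure", "graph_kind", "cutoff",
                  pooled_score = "score")
  dplyr::inner_join(site_part, pooled_part,
                    by = c("task", "measure", "graph_kind", "cutoff")) |>
    dplyr::mutate(difference = .data$mean_site_score - .data$pooled_score)
}

#' Discriminative maps for the well-classified grid cells
#'
#' For every non-skipped result whose balanced score is at or above the gate,
#' refits the classifier on all subjects of that cell and extracts the top
#' nodes by absolute hyperplane coefficient.
#'
#' @param experiment A [run_experiment()] result.
#' @param score_gate,fraction Override the config's gate / node fraction.
#' @param out_dir Optional directory; each map is written as a region-table
#'   CSV named after its grid cell.
#' @return Tibble of eligible cells with a `map` list-column of
#'   `discriminative_map` objects (zero rows when nothing passes the gate,
#'   with a message).
#' @export
make_maps <- function(experiment, score_gate = NULL, fraction = NULL,
                      out_dir = NULL) {
  stopifnot(inherits(experiment, "conn_experiment"))
  config <- experiment$config
  score_gate <- score_gate %||% config$map_score_gate
  fraction <- fraction %||% config$top_fraction
  eligible <- dplyr::filter(experiment$results, !.data$skipped,
                            .data$score >= score_gate)
  if (!nrow(eligible)) {
    message(sprintf("no grid cell reached the score gate (%.2f); no maps emitted",
                    score_gate))
    return(dplyr::mutate(eligible, map = list()))
  }
  maps <- purrr::pmap(
    dplyr::select(eligible, "task", "measure", "graph_kind", "cutoff", "scope",
                  "score"),
    function(task, measure, graph_kind, cutoff, scope, score) {
      tbl <- build_feature_table(experiment$centralities, measure, graph_kind,
                                 cutoff = if (is.na(cutoff)) NULL else cutoff,
                                 task = task, scope = scope)
      w <- fit_full_weights(tbl, cost = config$cost)
      if (isTRUE(attr(w, "degenerate"))) return(NULL)
      top_fraction(w, fraction = fraction, score = score,
                   score_gate = score_gate)
    }
  )
  keep <- !vapply(maps, is.null, logical(1))
  out <- dplyr::mutate(eligible[keep, ], map = maps[keep])
  if (!is.null(out_dir) && nrow(out)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(out))) {
      stem <- sprintf("map_%s_%s_%s%s_%s.csv", out$task[i], out$measure[i],
                      out$graph_kind[i],
                      ifelse(is.na(out$cutoff[i]), "",
                             sprintf("_%0.2f", out$cutoff[i])),
                      out$scope[i])
      export_map(out$map[[i]], file.path(out_dir, stem))
    }
  }
  out
}

#' Result-table-style score summary
#'
#' Pivots a results grid to the familiar wide layout: one row per measure
#' configuration, and per scope the integer-percent specificity, sensitivity
#' and balanced score (`NA` for skipped cells).
#'
#' @param x A `conn_experiment` or its results tibble.
#' @param task Which task to tabulate.
#' @return Wide tibble with columns `<scope>_spec`, `<scope>_sens`,
#'   `<scope>_score` per scope.
#' @export
report_scores <- function(x, task = "control_vs_adhd") {
  results <- if (inherits(x, "conn_experiment")) x$results else x
  results |>
    dplyr::filter(.data$task == !!task) |>
    dplyr::mutate(spec = ifelse(.data$skipped, NA_integer_,
                                report_percent(.data$specificity)),
                  sens = ifelse(.data$skipped, NA_integer_,
                                report_percent(.data$sensitivity)),
                  score = ifelse(.data$skipped, NA_integer_,
                                 report_percent(.data$score))) |>
    dplyr::select("measure", "graph_kind", "cutoff", "scope",
                  "spec", "sens", "score") |>
    tidyr::pivot_wider(names_from = "scope",
                       values_from = c("spec", "sens", "score"),
                       names_glue = "{scope}_{.value}")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
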