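test_that("the grid enumerates tasks x measure configs x scopes completely", {
  cfg <- experiment_config(small_spec(seed = 61), tasks = "control_vs_adhd")
  ex <- run_experiment(cfg)
  # 14 measure configurations x 3 scopes (2 sites + pooled)
  expect_equal(nrow(ex$results), 42)
  expect_equal(nrow(dplyr::distinct(ex$results, measure, graph_kind, cutoff)), 14)
  expect_setequal(unique(ex$results$scope), c("s1", "s2", "all"))
  expect_false(any(duplicated(
    ex$results[, c("task", "measure", "graph_kind", "cutoff", "scope")])))
  expect_true(all(ex$results$score[!ex$results$skipped] ==
                    (ex$results$sensitivity[!ex$results$skipped] +
                       ex$results$specificity[!ex$results$skipped]) / 2))
})

test_that("infeasible cells are recorded as explicit skips", {
  cfg <- experiment_config(small_spec(seed = 62, combined_at_s2 = 1),
                           measures = "degree", cutoffs = 0.15)
  ex <- run_experiment(cfg)
  bad <- dplyr::filter(ex$results, task == "inattentive_vs_combined", scope == "s2")
  expect_equal(nrow(bad), 2)              # weighted + one unweighted config
  expect_true(all(bad$skipped))
  expect_match(bad$skip_reason, "at least 2 per class")
  # the rest of the grid is intact
  expect_equal(nrow(ex$results), 2 * 2 * 3)
})

test_that("identical configs give byte-identical written results", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- small_spec(seed = 63)
  r1 <- run_experiment(experiment_config(spec, measures = c("degree", "burt"),
                                         cutoffs = 0.15, out_dir = d1))
  r2 <- run_experiment(experiment_config(spec, measures = c("degree", "burt"),
                                         cutoffs = 0.15, out_dir = d2))
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))
  expect_identical(r1$results, r2$results)
})

test_that("config seed overrides the cohort spec seed", {
  spec <- small_spec(seed = 1)
  a <- run_experiment(experiment_config(spec, measures = "degree",
                                        cutoffs = numeric(0),
                                        tasks = "control_vs_adhd", seed = 99))
  b <- run_experiment(experiment_config(small_spec(seed = 99), measures = "degree",
                                        cutoffs = numeric(0),
                                        tasks = "control_vs_adhd"))
  expect_identical(a$results, b$results)
})

test_that("mean-vs-pooled arithmetic and single-site identity hold", {
  grid <- tibble::tibble(
    task = "control_vs_adhd", measure = "degree", graph_kind = "weighted",
    cutoff = NA_real_, scope = c("s1", "s2", "all"),
    n_pos = 5L, n_neg = 5L, sensitivity = 0.5, specificity = 0.5,
    score = c(0.6, 0.7, 0.66), skipped = FALSE, skip_reason = NA_character_)
  cmp <- mean_vs_pooled(grid)
  expect_equal(cmp$mean_site_score, 0.65)
  expect_equal(cmp$pooled_score, 0.66)
  expect_equal(cmp$difference, -0.01)
  expect_equal(cmp$n_sites, 2L)

  single <- dplyr::filter(grid, scope != "s2")
  expect_equal(mean_vs_pooled(single)$mean_site_score, 0.6)

  # measures lacking a pooled record are dropped
  no_pool <- dplyr::filter(grid, scope != "all")
  expect_equal(nrow(mean_vs_pooled(no_pool)), 0)
})

test_that("maps are gated by score and disabling the gate maps every cell", {
  cfg <- experiment_config(small_spec(seed = 64, effect_size = 0.3),
                           measures = "degree", cutoffs = 0.15,
                           tasks = "control_vs_adhd")
  ex <- run_experiment(cfg)

  expect_message(none <- make_maps(ex, score_gate = 1.01), "no grid cell")
  expect_equal(nrow(none), 0)

  all_maps <- make_maps(ex, score_gate = 0)
  feasible <- sum(!ex$results$skipped)
  expect_equal(nrow(all_maps), feasible)
  expect_true(all(vapply(all_maps$map, inherits, logical(1), "discriminative_map")))
  expect_true(all(vapply(all_maps$map, function(m) m$k, integer(1)) ==
                    ceiling(0.05 * 30)))

  d <- withr::local_tempdir()
  gated <- make_maps(ex, score_gate = min(all_maps$score), out_dir = d)
  expect_equal(nrow(gated), feasible)
  expect_length(list.files(d, pattern = "^map_.*csv$"), feasible)
})

test_that("score reports pivot to the familiar wide table", {
  cfg <- experiment_config(small_spec(seed = 65), measures = "degree",
                           cutoffs = 0.15, tasks = "control_vs_adhd")
  ex <- run_experiment(cfg)
  rep_tab <- report_scores(ex, task = "control_vs_adhd")
  expect_equal(nrow(rep_tab), 2)  # weighted degree + unweighted degree @0.15
  expect_true(all(c("s1_spec", "s1_sens", "s1_score",
                    "all_spec", "all_sens", "all_score") %in% names(rep_tab)))
  expect_true(all(rep_tab$all_score >= 0 & rep_tab$all_score <= 100))
})

test_that("experiments resolve cohorts from specs, tibbles and manifests", {
  spec <- small_spec(seed = 66, effect_size = 0)
  coh <- simulate_cohort(spec)
  d <- withr::local_tempdir()
  manifest <- write_cohort(coh, d)

  base_cfg <- function(cohort) {
    experiment_config(cohort, measures = "degree", cutoffs = numeric(0),
                      tasks = "control_vs_adhd", scopes = "all")
  }
  from_spec <- run_experiment(base_cfg(spec))
  from_tbl <- run_experiment(base_cfg(coh))
  from_path <- run_experiment(base_cfg(manifest))
  expect_identical(from_spec$results, from_tbl$results)
  # text roundtrip truncates to write.table precision; scores must agree
  expect_equal(from_path$results$score, from_tbl$results$score, tolerance = 1e-6)
})

test_that("experiment tidiers and the comparison plot are well-formed", {
  cfg <- experiment_config(small_spec(seed = 67), measures = c("degree", "closeness"),
                           cutoffs = 0.15)
  ex <- run_experiment(cfg)
  expect_identical(tidy(ex), ex$results)
  gl <- glance(ex)
  expect_equal(gl$n_cells, nrow(ex$results))
  expect_equal(gl$n_subjects, 30)
  expect_s3_class(autoplot(ex), "ggplot")
})
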