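# Construct feature tables directly from a matrix and labels, bypassing the
# centrality pipeline, for classifier-focused tests.
make_table <- function(x, labels, positive_class = levels(labels)[2],
                       task = "control_vs_adhd", scope = "all",
                       sites = rep("s1", nrow(x))) {
  stopifnot(is.factor(labels))
  if (is.null(rownames(x))) rownames(x) <- sprintf("subj%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("roi_%d", seq_len(ncol(x)))
  structure(
    list(x = x, labels = labels, sites = sites,
         positive_class = positive_class, task = task, scope = scope,
         measure = "degree", graph_kind = "weighted", cutoff = NA_real_),
    class = "feature_table"
  )
}

# two-class Gaussian feature table: class means +/- separation/2 on every
# informative column
make_gaussian_table <- function(n_per_class = 10, p = 5, separation = 0,
                                informative = seq_len(p)) {
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  shift <- rep(c(-separation / 2, separation / 2), each = n_per_class)
  for (j in informative) x[, j] <- x[, j] + shift
  labels <- factor(rep(c("neg", "pos"), each = n_per_class),
                   levels = c("neg", "pos"))
  make_table(x, labels)
}

# small cohort spec used across harness tests: 2 sites, 3 groups, 30 ROIs
small_spec <- function(seed = 7, effect_size = 0.25, effect_nodes = 1:4,
                       combined_at_s2 = 4) {
  cohort_spec(
    n_rois = 30, n_modules = 3,
    sites = list(
      site_spec("s1", c(control = 6, inattentive = 5, combined = 5),
                noise_sd = 0.8, n_timepoints = 80),
      site_spec("s2", c(control = 6, inattentive = 4, combined = combined_at_s2),
                noise_sd = 1.0, n_timepoints = 60)
    ),
    within_module_corr = 0.3, between_module_corr = 0.05,
    effect_nodes = effect_nodes, effect_size = effect_size, seed = seed
  )
}
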