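# Synthetic multi-site cohorts: latent block-modular correlation structure with
# node-localized group perturbations, sampled as i.i.d. multivariate normal
# "timepoints" per subject.

#' Describe one acquisition site of a synthetic cohort
#'
#' A site contributes a fixed number of subjects per diagnostic group, its own
#' observation-noise level and its own scan length. Site-to-site differences in
#' `noise_sd` and `n_timepoints` are the generator's model of between-site
#' heterogeneity (different scanners, protocols and scan durations).
#'
#' @param site_id Character label for the site.
#' @param n_per_group Named integer vector of subject counts, one entry per
#'   group label (e.g. `c(control = 10, inattentive = 5, combined = 5)`).
#'   Zero counts are allowed.
#' @param noise_sd Standard deviation of isotropic observation noise added to
#'   the latent covariance (so the subject-level target correlation is the
#'   latent correlation attenuated by `1 / (1 + noise_sd^2)`).
#' @param n_timepoints Number of timepoints sampled for every subject at this
#'   site. May be smaller than the number of ROIs; downstream correlation
#'   estimation tolerates rank deficiency.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_id, n_per_group, noise_sd = 1, n_timepoints = 150) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    abort("`n_per_group` must be a named vector (one count per group label).")
  }
  if (any(n_per_group < 0)) abort("group counts must be >= 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (n_timepoints < 3) abort("`n_timepoints` must be >= 3")
  structure(
    list(
      site_id = site_id,
      n_per_group = as.integer(n_per_group) |> stats::setNames(names(n_per_group)),
      noise_sd = noise_sd,
      n_timepoints = as.integer(n_timepoints)
    ),
    class = "site_spec"
  )
}

#' Default five-site layout of a synthetic cohort
#'
#' Five sites with unequal group sizes summing to 340 controls, 159
#' inattentive and 110 combined subjects (the cohort totals of the multi-site
#' ADHD resting-state sample the generator emulates); per-site splits are
#' plausible inventions, including one site with a single combined-type
#' subject so that subtype classification is infeasible there.
#'
#' @return List of [site_spec()] objects.
#' @export
default_sites <- function() {
  list(
    site_spec("siteA", c(control = 116, inattentive = 31, combined = 29),
              noise_sd = 1.0, n_timepoints = 230),
    site_spec("siteB", c(control = 61, inattentive = 12, combined = 10),
              noise_sd = 1.2, n_timepoints = 120),
    site_spec("siteC", c(control = 23, inattentive = 17, combined = 1),
              noise_sd = 0.8, n_timepoints = 250),
    site_spec("siteD", c(control = 98, inattentive = 44, combined = 53),
              noise_sd = 1.1, n_timepoints = 170),
    site_spec("siteE", c(control = 42, inattentive = 55, combined = 17),
              noise_sd = 0.9, n_timepoints = 100)
  )
}

#' Specify a synthetic multi-site cohort
#'
#' The latent signal covariance is block-modular (contiguous communities with
#' constant within/between correlation); group membership perturbs, additively,
#' every correlation incident to the `effect_nodes`, scaled per group by
#' `effect_scale`, and the result is projected back to a valid correlation
#' matrix. Each subject's time series is an i.i.d. multivariate normal sample
#' from their group's covariance plus site-specific white noise.
#'
#' @param n_rois Number of regions of interest (graph nodes).
#' @param sites List of [site_spec()] objects.
#' @param groups Character vector of group labels; every site's `n_per_group`
#'   names must be a subset of it.
#' @param n_modules Number of latent communities (contiguous index blocks;
#'   remainder ROIs are assigned to the last block).
#' @param within_module_corr,between_module_corr Latent correlations inside and
#'   across modules; `0 <= between <= within < 1`.
#' @param effect_nodes Integer vector of 1-based ROI indices carrying the
#'   planted group difference (empty for a null cohort).
#' @param effect_size Additive correlation shift at the effect nodes, in
#'   (-1, 1); per-group magnitude is `effect_size * effect_scale[group]`.
#' @param effect_scale Named multipliers of `effect_size` per group. The
#'   default (control 0, inattentive 0.5, combined 1) puts signal in both the
#'   control-vs-patient and the subtype contrast.
#' @param seed Master integer seed; per-subject seeds are derived from it,
#'   the site index and the within-site subject index, so the cohort is
#'   bit-reproducible and subjects can be simulated in any order.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rois = 400,
                        sites = default_sites(),
                        groups = c("control", "inattentive", "combined"),
                        n_modules = 8,
                        within_module_corr = 0.3,
                        between_module_corr = 0.05,
                        effect_nodes = integer(0),
                        effect_size = 0,
                        effect_scale = c(control = 0, inattentive = 0.5, combined = 1),
                        seed = 1L) {
  stopifnot(n_rois >= 2, n_modules >= 1)
  if (!all(vapply(sites, inherits, logical(1), "site_spec"))) {
    abort("`sites` must be a list of site_spec objects")
  }
  for (s in sites) {
    bad <- setdiff(names(s$n_per_group), groups)
    if (length(bad)) abort(paste0("site '", s$site_id, "' names unknown group(s): ",
                                  paste(bad, collapse = ", ")))
  }
  if (length(effect_nodes)) {
    effect_nodes <- as.integer(effect_nodes)
    if (any(effect_nodes < 1L | effect_nodes > n_rois)) {
      abort("`effect_nodes` must be 1-based ROI indices within 1..n_rois")
    }
  }
  if (abs(effect_size) >= 1) abort("`effect_size` must lie in (-1, 1)")
  missing_scale <- setdiff(groups, names(effect_scale))
  if (length(missing_scale)) {
    abort(paste0("`effect_scale` missing group(s): ", paste(missing_scale, collapse = ", ")))
  }
  structure(
    list(
      n_rois = as.integer(n_rois), sites = sites, groups = groups,
      n_modules = as.integer(n_modules),
      within_module_corr = within_module_corr,
      between_module_corr = between_module_corr,
      effect_nodes = as.integer(effect_nodes), effect_size = effect_size,
      effect_scale = effect_scale, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Block-modular latent correlation matrix
#'
#' Contiguous index blocks with constant correlation `within_module_corr`
#' inside a block and `between_module_corr` across blocks, unit diagonal.
#' For `0 <= between <= within < 1` such block-constant matrices are
#' positive semidefinite by construction; this is verified by
#' eigendecomposition and violated parameter combinations are rejected.
#'
#' @inheritParams cohort_spec
#' @return Symmetric `n_rois` x `n_rois` correlation matrix.
#' @export
make_base_covariance <- function(n_rois, n_modules,
                                 within_module_corr, between_module_corr) {
  if (!(between_module_corr >= 0 && between_module_corr <= within_module_corr &&
        within_module_corr < 1)) {
    abort("need 0 <= between_module_corr <= within_module_corr < 1")
  }
  if (n_modules > n_rois) abort("`n_modules` cannot exceed `n_rois`")
  module <- module_assignment(n_rois, n_modules)
  same <- outer(module, module, "==")
  m <- matrix(between_module_corr, n_rois, n_rois)
  m[same] <- within_module_corr
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort(sprintf("parameter combination yields a non-PSD matrix (min eigenvalue %.3g)",
                  min(ev)))
  }
  m
}

# contiguous blocks, remainder ROIs folded into the last module
module_assignment <- function(n_rois, n_modules) {
  size <- n_rois %/% n_modules
  module <- rep(seq_len(n_modules), each = size, length.out = n_modules * size)
  c(module, rep(n_modules, n_rois - length(module)))
}

#' Plant a node-localized group effect into a correlation matrix
#'
#' Shifts every off-diagonal entry incident to at least one effect node by
#' `effect_size`, clips to \[-0.99, 0.99\], and projects back to the nearest
#' valid correlation matrix (eigenvalue clipping at zero followed by
#' re-standardization to unit diagonal). With `effect_size = 0` the input is
#' returned unchanged.
#'
#' @param base Valid correlation matrix (symmetric, unit diagonal, PSD).
#' @param effect_nodes 1-based node indices receiving the perturbation.
#' @param effect_size Additive correlation shift in (-1, 1).
#' @return Correlation matrix of the same dimension.
#' @export
apply_group_effect <- function(base, effect_nodes, effect_size) {
  validate_correlation(base)
  if (effect_size == 0) return(base)
  if (!length(effect_nodes)) {
    warn("`effect_nodes` is empty; returning `base` unchanged")
    return(base)
  }
  n <- nrow(base)
  effect_nodes <- as.integer(effect_nodes)
  stopifnot(all(effect_nodes >= 1L), all(effect_nodes <= n))
  hit <- matrix(FALSE, n, n)
  hit[effect_nodes, ] <- TRUE
  hit[, effect_nodes] <- TRUE
  diag(hit) <- FALSE
  out <- base
  out[hit] <- pmin(pmax(out[hit] + effect_size, -0.99), 0.99)
  nearest_psd_corr(out)
}

# eigenvalue clipping at 0, then D^{-1/2} S D^{-1/2} to restore unit diagonal
nearest_psd_corr <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  s <- e$vectors %*% (lam * t(e$vectors))
  d <- diag(s)
  if (any(d <= 0)) abort("degenerate projection: zero diagonal after PSD clipping")
  s <- s / sqrt(outer(d, d))
  diag(s) <- 1
  (s + t(s)) / 2
}

validate_correlation <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("expected a square matrix")
  if (max(abs(m - t(m))) > 1e-8) abort("matrix is not symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) abort("diagonal must be 1")
  invisible(m)
}

# eigen-based factor L with cov = L %*% t(L); cached by callers so the
# decomposition is done once per distinct covariance
cov_factor <- function(cov) {
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    abort("covariance is not positive semidefinite")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(cov))
}

#' Simulate one subject's ROI time series
#'
#' Draws `n_timepoints` independent samples from a zero-mean multivariate
#' normal with covariance `cov + noise_sd^2 * I`. A fixed seed yields
#' bit-identical output.
#'
#' @param cov Symmetric positive semidefinite signal covariance.
#' @param n_timepoints Number of rows to draw (>= 3).
#' @param noise_sd Isotropic observation-noise standard deviation.
#' @param seed Integer seed for this subject.
#' @param .factor Optional precomputed factor `L` of `cov + noise_sd^2 I`
#'   with `L %*% t(L)` equal to it (performance hook for cohort simulation;
#'   results are identical with or without it).
#' @return Numeric matrix, `n_timepoints` x `ncol(cov)`.
#' @export
simulate_subject <- function(cov, n_timepoints, noise_sd, seed, .factor = NULL) {
  stopifnot(n_timepoints >= 3)
  n <- ncol(cov)
  if (is.null(.factor)) {
    .factor <- cov_factor(cov + diag(noise_sd^2, n))
  }
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n_timepoints * n), n_timepoints, n)
  z %*% t(.factor)
}

subject_seed <- function(master, site_idx, subj_idx) {
  as.integer((as.numeric(master) + site_idx * 100000007 + subj_idx * 101) %% 2147483647)
}

#' Simulate a full multi-site cohort
#'
#' One subject record per site, group and count; per-subject seeds are derived
#' deterministically from `spec$seed`, the site index and the within-site
#' subject index, so the whole cohort is reproducible bit-exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `site`, `group` and a
#'   list-column `timeseries` of `n_timepoints` x `n_rois` matrices.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  total <- sum(vapply(spec$sites, function(s) sum(s$n_per_group), numeric(1)))
  if (total == 0) abort("cohort spec yields zero subjects")
  base <- make_base_covariance(spec$n_rois, spec$n_modules,
                               spec$within_module_corr, spec$between_module_corr)
  group_cov <- lapply(stats::setNames(nm = spec$groups), function(g) {
    delta <- spec$effect_size * spec$effect_scale[[g]]
    if (delta == 0 || !length(spec$effect_nodes)) base
    else apply_group_effect(base, spec$effect_nodes, delta)
  })
  rows <- list()
  for (si in seq_along(spec$sites)) {
    site <- spec$sites[[si]]
    factors <- list()  # per-group factor of cov + sd^2 I, computed lazily
    subj_idx <- 0L
    for (g in names(site$n_per_group)) {
      ng <- site$n_per_group[[g]]
      if (ng == 0L) next
      if (is.null(factors[[g]])) {
        factors[[g]] <- cov_factor(group_cov[[g]] + diag(site$noise_sd^2, spec$n_rois))
      }
      for (k in seq_len(ng)) {
        subj_idx <- subj_idx + 1L
        ts <- simulate_subject(group_cov[[g]], site$n_timepoints, site$noise_sd,
                               seed = subject_seed(spec$seed, si, subj_idx),
                               .factor = factors[[g]])
        rows[[length(rows) + 1L]] <- tibble(
          subject_id = sprintf("%s_%s_%03d", site$site_id, g, k),
          site = site$site_id, group = g, timeseries = list(ts)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
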