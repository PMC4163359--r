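---
title: "Centrality-based classification of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality-based classification of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centconn)
library(dplyr)
```

## The pipeline

`centconn` implements a graph-theoretic classification analysis of
resting-state functional connectivity. Each subject contributes a matrix of
regional (ROI) time series over a fixed parcellation. The analysis proceeds
in four stages:

1. **Connectivity.** The Pearson correlation between every ROI pair is the
   functional-connectivity estimate. The correlation matrix is used directly
   as the adjacency of an undirected *weighted* graph, and is additionally
   binarized at three cut-offs (0.1, 0.15, 0.25) into unweighted graphs.
   Cut-offs in this range keep the binary networks from fragmenting into
   granular components; edge sets are nested across cut-offs by construction.
2. **Centrality features.** Five node-centrality families are computed:
   degree (strength on weighted graphs), closeness, betweenness, eigenvector
   centrality and Burt's constraint. Eigenvector centrality and Burt's
   constraint are computed on weighted graphs only; degree, closeness and
   betweenness on both kinds, giving 5 + 3 × 3 = **14 feature vectors per
   subject**. Each vector (subjects × ROIs) is one classifier input.
3. **Classification.** A linear support vector machine is evaluated by
   leave-one-subject-out cross-validation, separately per acquisition site
   and pooled across sites, for two tasks: typical controls versus all
   patients, and the inattentive versus combined patient subtypes. Accuracy
   is summarized by the balanced score
   (sensitivity + specificity)/2, robust to the strong class imbalance
   typical of clinical cohorts.
4. **Discriminative mapping.** The classifier refitted on *all* subjects
   yields one hyperplane coefficient per ROI; ranking ROIs by absolute
   coefficient and keeping the top 5% (20 of 400) gives the discriminative
   map. By convention maps are reported only for classifications whose
   balanced score reaches 0.70.

## Graph and centrality conventions

The source correlations are similarities, so shortest-path measures need a
similarity-to-cost transform; we use edge length = 1/weight, fixed
project-wide. Other conventions, chosen where the underlying definitions
leave freedom and applied everywhere:

- **Negative correlations** are excluded from the weighted graph (clipped to
  0). Eigenvector centrality relies on the Perron–Frobenius guarantee and
  Burt's constraint on a proportional-investment interpretation, both of
  which need nonnegative weights; the positive binarization cut-offs point
  the same way. `to_weighted_graph()` records how many pairs were clipped so
  the alternative convention can be studied.
- **Binarization is strict** (`r > cutoff`), and no Fisher z-transform or
  absolute value is applied before thresholding.
- **Closeness on disconnected graphs** is the reciprocal mean distance over
  the *reachable* set (isolated nodes score 0), avoiding infinite distances
  while preserving within-component ordering.
- **Betweenness** uses Freeman fractional pair counting, unnormalized —
  feature standardization in the classifier makes scale irrelevant.
- **Eigenvector centrality** is computed per connected component by shifted
  power iteration (`A + 0.1·max(strength)·I`), which has the same
  eigenvectors as `A` but a strictly dominant leading eigenvalue even on
  bipartite-spectrum graphs (stars, even cycles) where the plain iteration
  oscillates. Working per component matters on disconnected graphs: the
  leading eigenvector is supported on the component with the largest leading
  eigenvalue, and a global iteration leaves slowly-decaying contamination on
  near-dominant components. Per component: tolerance 1e-10 in sup-norm,
  uniform start vector; non-dominant components score exactly 0, and
  components whose leading eigenvalues tie within relative 1e-8 are all
  retained. Values are rescaled to max = 1.
- **Burt's constraint** for an isolated node is defined as 0 and flagged,
  keeping feature matrices complete.

All measures are validated against independent brute-force references
(Floyd–Warshall distances with pair-splitting betweenness, dense
eigendecomposition, direct formula loops) and against igraph on random
graphs; tolerance 1e-8.

## Classifier choices

The SVM uses a linear kernel with cost C = 1, exposed in the configuration
but never tuned on test folds — no hyperparameter search, feature selection
or class weighting is performed. Centrality families live on wildly
different scales (betweenness can reach hundreds while Burt's constraint
stays near 1), and max-margin classifiers are scale-sensitive, so features
are standardized per fold using **training-fold statistics only**; the
held-out row is transformed with the same statistics, which a leakage test
verifies. Degenerate situations resolve deterministically: a single-class
training fold predicts that class; identical feature rows trigger a
training-majority prediction (ties to the control/negative class), which is
what produces the characteristic (100%, 0%, 50%) triple when a feature
carries no information — on dense correlation graphs Burt's constraint is
nearly constant across subjects, and this is exactly the pattern a constant
feature produces.

The positive class is always the patient group (all patients in task 1, the
combined subtype in task 2), so "sensitivity" uniformly means patient
detection. Reported percentages round half away from zero, reproducing e.g.
77% from the pair (78%, 75%).

## The synthetic cohort generator

No imaging data ships with the package; a generative model stands in for a
multi-site clinical cohort so every downstream stage is testable:

- The latent signal correlation is **block-modular**: contiguous communities
  (default 8 over 400 ROIs) with constant within-module correlation 0.3 and
  between-module correlation 0.05. Block-constant matrices in this range
  are provably positive semidefinite, giving closed-form validity — the
  blocks emulate the stable correlated networks of the resting brain, not
  any estimated network layout.
- **Group differences are node-localized**: every correlation incident to a
  chosen effect-node set is shifted additively (default scaling: controls
  0×, inattentive 0.5×, combined 1×), clipped to ±0.99, and the matrix is
  projected back to a valid correlation matrix by eigenvalue clipping and
  re-standardization. This is the simplest mechanism under which centrality
  at specific nodes discriminates groups.
- **Subjects are i.i.d. multivariate normal draws** from their group's
  covariance plus isotropic site noise `noise_sd² · I`. Adding noise to the
  covariance rather than to the series keeps the subject-level target
  correlation analytically known (attenuated by `1/(1 + noise_sd²)`).
  Per-subject seeds derive deterministically from the master seed, site
  index and subject index, so cohorts are bit-reproducible in any
  simulation order.
- The **default layout** mirrors a five-site cohort of 609 subjects
  (340 controls, 159 inattentive, 110 combined) with unequal site sizes,
  per-site noise levels of 0.8–1.2 and scan lengths of 100–250 timepoints;
  one site contributes a single combined-type subject, so subtype
  classification is infeasible there and the experiment grid records an
  explicit skip. Per-site splits are plausible inventions: only cohort
  totals are documented for the real sample.

What the generator deliberately does *not* model: hemodynamics, temporal
autocorrelation, motion artifacts, non-Gaussian tails, or voxel-level
structure. Passing tests therefore demonstrate correctness of the pipeline
and its calibration under idealized signal/noise assumptions, not expected
accuracy on real resting-state data — real between-group effects are weaker
and less localized, and real site heterogeneity is richer than an SD knob.

## Calibration and recovery checks

Two simulation studies are wired into the test suite, with sizes chosen to
keep a full run comfortably interactive:

- **Null calibration**: 100 effect-free cohorts of 30 + 30 subjects, 100
  ROIs, 100 timepoints, noise SD 1. Mean leave-one-out balanced score over
  weighted-degree features must fall in 0.5 ± 0.05. (Leave-one-out on
  balanced classes has a small pessimistic bias — the training fold always
  under-represents the held-out subject's class — so means land slightly
  below 0.5.)
- **Signal recovery**: 20 cohorts of 40 + 40 subjects, 400 ROIs, 200
  timepoints, noise SD 0.5, with +0.3 planted on 10 nodes. The pooled
  weighted-degree score must exceed 0.6 in the majority of replicates, and
  the top-5% map (20 nodes) must overlap the planted 10 above the
  hypergeometric chance expectation of 0.5 nodes in at least 90% of
  replicates.

## Numerical details worth knowing

- Shortest-path tie detection uses a relative tolerance of 1e-10 when
  counting path multiplicities on real-valued lengths.
- PSD projection clips eigenvalues at 0 and re-standardizes the diagonal;
  with a zero effect the input is returned exactly (no projection rounding).
- Correlation estimation tolerates more ROIs than timepoints; only constant
  (zero-variance) series are rejected, by ROI index.
- Zero-variance features inside a cross-validation fold are centered but not
  scaled (unit divisor), so they carry no information rather than NaNs.
- The `k = ceiling(fraction · n)` rule makes the top-5% selection exact at
  n = 400 (k = 20) and well-defined for any parcellation; ranking ties break
  by ascending ROI index so maps are reproducible.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(
  n_rois = 100, n_modules = 4,
  sites = list(
    site_spec("siteA", c(control = 20, inattentive = 10, combined = 10),
              noise_sd = 0.8, n_timepoints = 150),
    site_spec("siteB", c(control = 15, inattentive = 8, combined = 8),
              noise_sd = 1.1, n_timepoints = 120)
  ),
  effect_nodes = 1:8, effect_size = 0.25, seed = 1
)

experiment <- run_experiment(experiment_config(spec))
tidy(experiment)                      # the full results grid
mean_vs_pooled(experiment)            # site-mean vs pooled comparison
autoplot(experiment)                  # the per-measure comparison figure

maps <- make_maps(experiment)         # gated at balanced score >= 0.70
maps$map[[1]]
autoplot(maps$map[[1]])
```

## Limitations

Exact replication of published accuracies on the real multi-site cohort is
out of scope: the upstream preprocessing, atlas construction and the
original SVM software/hyperparameters are not part of this package, and the
original cost parameter is undocumented. What the package guarantees is the
arithmetic of the scoring and mapping conventions, oracle-verified
centrality implementations, a calibrated null, and end-to-end recovery of
planted effects under the stated generative model.
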