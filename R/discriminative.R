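# Discriminative-node mapping: hyperplane coefficients of the classifier
# trained on all subjects, ranked by magnitude, top 5% selected.

#' Hyperplane coefficients of the fully trained classifier
#'
#' Trains the linear maximum-margin classifier on *all* subjects (not the
#' leave-one-out folds), with the same standardization and cost as
#' [loocv_classify()], and returns the per-feature coefficients of the
#' separating hyperplane in the standardized-feature space (ranking raw-space
#' weights would conflate feature scale with importance).
#'
#' @param table A [build_feature_table()] result.
#' @param cost SVM regularization constant.
#' @return Numeric weight vector, one entry per ROI, with attribute
#'   `degenerate` (TRUE when the table is untrainable — a single class or
#'   identical feature rows — in which case all weights are zero).
#' @export
fit_full_weights <- function(table, cost = 1) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  y <- droplevels(table$labels)
  p <- ncol(x)
  degenerate_out <- function() {
    w <- numeric(p)
    names(w) <- colnames(x)
    attr(w, "degenerate") <- TRUE
    w
  }
  if (nlevels(y) < 2L) return(degenerate_out())
  scaler <- fold_scaler(x)
  xs <- scale_with(x, scaler)
  if (max(abs(xs)) < 1e-10) return(degenerate_out())
  fit <- svm_fit(xs, y, cost)
  w <- drop(crossprod(fit$coefs, fit$SV))
  names(w) <- colnames(x)
  attr(w, "degenerate") <- FALSE
  w
}

#' Select the most discriminative nodes from a weight vector
#'
#' Ranks nodes by absolute hyperplane coefficient (ties broken by ascending
#' node index, making the selection deterministic) and keeps the top
#' `ceiling(fraction * n)` — 20 nodes for the canonical 400-ROI parcellation
#' at the default 5%. An optional balanced score and gate are recorded as
#' metadata: by convention maps are reported only for classifications scoring
#' at or above the gate (default 0.70), but the selection itself is always
#' computed.
#'
#' @param weights Numeric weight vector (e.g. from [fit_full_weights()]);
#'   must not be all zero.
#' @param fraction Fraction of nodes to keep, in (0, 1\].
#' @param score,score_gate Optional metadata: the balanced score of the
#'   underlying classification and the reporting gate it is compared against.
#' @return A `discriminative_map`: `weights`, `ranking` (permutation of
#'   1..n by descending `|weight|`), `selected` (the leading
#'   `ceiling(fraction * n)` indices), `k`, and gate metadata.
#' @export
top_fraction <- function(weights, fraction = 0.05, score = NULL,
                         score_gate = 0.70) {
  if (!is.numeric(weights) || !length(weights)) abort("`weights` must be a numeric vector")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1]")
  if (all(weights == 0)) abort("all weights are zero; nothing to rank")
  n <- length(weights)
  ranking <- order(-abs(weights), seq_len(n))
  k <- as.integer(ceiling(fraction * n))
  structure(
    list(weights = as.numeric(weights), roi = seq_len(n), ranking = ranking,
         selected = ranking[seq_len(k)], k = k, fraction = fraction,
         score = score, score_gate = score_gate,
         passes_gate = if (is.null(score)) NA else score >= score_gate),
    class = "discriminative_map"
  )
}

#' @export
print.discriminative_map <- function(x, ...) {
  cat(sprintf("<discriminative_map> top %d of %d nodes (fraction %.3g)\n",
              x$k, length(x$weights), x$fraction))
  if (!is.null(x$score)) {
    cat(sprintf("  score %.3f %s gate %.2f\n", x$score,
                if (isTRUE(x$passes_gate)) ">=" else "<", x$score_gate))
  }
  cat("  selected:", paste(utils::head(x$selected, 10), collapse = ", "),
      if (x$k > 10) "..." else "", "\n")
  invisible(x)
}

#' Export a discriminative map as a region table
#'
#' Writes one CSV row per selected node: `rank`, `roi_index` (1-based),
#' `weight`, `abs_weight`, and `atlas_label` when labels are supplied.
#'
#' @param map A [top_fraction()] result.
#' @param file Output CSV path (`NULL` to return the table without writing).
#' @param atlas_labels Optional character vector of region names, one per
#'   node of the full parcellation (length must match the weight vector).
#' @return The region table (tibble), invisibly when written.
#' @export
export_map <- function(map, file = NULL, atlas_labels = NULL) {
  stopifnot(inherits(map, "discriminative_map"))
  n <- length(map$weights)
  if (!is.null(atlas_labels) && length(atlas_labels) != n) {
    abort(sprintf("atlas has %d labels but the map covers %d nodes",
                  length(atlas_labels), n))
  }
  sel <- map$selected
  out <- tibble(rank = seq_along(sel), roi_index = sel,
                weight = map$weights[sel], abs_weight = abs(map$weights[sel]))
  if (!is.null(atlas_labels)) out$atlas_label <- atlas_labels[sel]
  if (is.null(file)) return(out)
  write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Export a discriminative map as a volumetric label image
#'
#' Given an integer-labeled parcellation volume (NIfTI) whose labels
#' 1..n index the ROIs, writes a volume in which voxels of each selected ROI
#' carry that ROI's rank and all other voxels are 0. Strictly optional:
#' synthetic analyses need no imaging files.
#'
#' @param map A [top_fraction()] result.
#' @param parcellation Path to (or `RNifti` image of) the integer-labeled
#'   parcellation; its maximum label must equal the number of nodes.
#' @param file Output NIfTI path.
#' @return Invisibly, `file`.
#' @export
export_map_volume <- function(map, parcellation, file) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("volumetric export requires the RNifti package")
  }
  img <- if (is.character(parcellation)) RNifti::readNifti(parcellation) else parcellation
  labels <- as.integer(round(max(img)))
  n <- length(map$weights)
  if (labels != n) {
    abort(sprintf("parcellation has %d labels but the map covers %d nodes", labels, n))
  }
  rank_of <- integer(n)
  rank_of[map$selected] <- seq_along(map$selected)
  arr <- array(0L, dim = dim(img))
  in_roi <- img >= 1
  arr[in_roi] <- rank_of[as.integer(round(img[in_roi]))]
  RNifti::writeNifti(RNifti::asNifti(arr, reference = img), file)
  invisible(file)
}
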