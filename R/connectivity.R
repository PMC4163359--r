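# From ROI time series to graphs: one Pearson correlation matrix per subject,
# equated with the adjacency of an undirected weighted graph, plus binary
# graphs at fixed correlation cut-offs.

#' Pearson correlation matrix of an ROI time-series matrix
#'
#' @param timeseries Numeric matrix, timepoints x ROIs, at least 3 rows.
#'   Columns with zero variance are rejected (correlation undefined).
#' @return Symmetric correlation matrix with diagonal exactly 1.
#' @export
correlation_matrix <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3) abort("need at least 3 timepoints")
  if (anyNA(timeseries)) abort("time series contains missing values")
  sds <- apply(timeseries, 2, sd)
  flat <- which(sds == 0)
  if (length(flat)) {
    abort(sprintf("constant time series (zero variance) at ROI index %s",
                  paste(flat, collapse = ", ")))
  }
  cm <- cor(timeseries)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  dimnames(cm) <- NULL
  cm
}

#' Weighted graph adjacency from a correlation matrix
#'
#' The correlation matrix is used directly as the adjacency of an undirected
#' weighted graph, with the diagonal zeroed and negative correlations clipped
#' to zero (eigenvector centrality and Burt's constraint presume nonnegative
#' weights, and the positive cut-offs of the binarized graphs indicate
#' positive-correlation edges). The number of clipped node pairs is recorded
#' in attribute `n_clipped` so the convention's impact can be audited.
#'
#' @param cm Correlation matrix from [correlation_matrix()].
#' @return Nonnegative symmetric adjacency matrix, zero diagonal, with
#'   attribute `n_clipped` (count of negative off-diagonal pairs set to 0).
#' @export
to_weighted_graph <- function(cm) {
  validate_correlation(cm)
  adj <- cm
  diag(adj) <- 0
  n_clipped <- sum(adj[upper.tri(adj)] < 0)
  adj[adj < 0] <- 0
  attr(adj, "n_clipped") <- n_clipped
  adj
}

#' Binarize a correlation matrix at a cut-off
#'
#' An edge is present iff the correlation strictly exceeds the cut-off
#' (convention fixed project-wide); edge sets are therefore nested across
#' decreasing cut-offs.
#'
#' @param cm Correlation matrix.
#' @param cutoff Threshold in (0, 1); the canonical battery uses
#'   0.1, 0.15 and 0.25.
#' @return 0/1 adjacency matrix with zero diagonal and attribute `cutoff`.
#' @export
binarize <- function(cm, cutoff) {
  validate_correlation(cm)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1) {
    abort("`cutoff` must be a single value in (0, 1)")
  }
  adj <- (cm > cutoff) * 1
  diag(adj) <- 0
  adj <- pmax(adj, t(adj))
  attr(adj, "cutoff") <- cutoff
  adj
}
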