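# Node centrality measures, implemented from first principles on dense
# adjacency matrices. Weighted graphs carry correlation weights (similarities);
# shortest-path measures convert them to costs via length = 1/weight, the
# standard similarity-to-distance transform. Binary graphs have unit lengths.

validate_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) abort("expected a square adjacency matrix")
  if (max(abs(adj - t(adj))) > 1e-10) abort("adjacency must be symmetric")
  if (any(adj < 0)) abort("adjacency weights must be nonnegative")
  if (any(diag(adj) != 0)) abort("adjacency diagonal must be zero")
  invisible(adj)
}

edge_lengths <- function(adj) {
  lens <- 1 / adj
  lens[adj <= 0] <- Inf
  diag(lens) <- Inf
  lens
}

# Single-source shortest paths (Dijkstra on dense lengths) with shortest-path
# counts and predecessor lists; ties in path length compared at relative
# tolerance 1e-10 so weighted graphs with exactly equal alternative routes
# count multiplicities correctly.
single_source_sp <- function(lens, s) {
  n <- nrow(lens)
  dist <- rep(Inf, n)
  dist[s] <- 0
  sigma <- numeric(n)
  sigma[s] <- 1
  preds <- vector("list", n)
  done <- logical(n)
  visit_order <- integer(n)
  n_done <- 0L
  repeat {
    d <- dist
    d[done] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    n_done <- n_done + 1L
    visit_order[n_done] <- u
    for (v in which(is.finite(lens[u, ]) & !done)) {
      alt <- dist[u] + lens[u, v]
      tol <- 1e-10 * max(1, abs(alt))
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (alt <= dist[v] + tol) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds,
       order = visit_order[seq_len(n_done)])
}

# closeness and betweenness share the all-sources pass (Brandes accumulation)
sp_centralities <- function(adj) {
  validate_adjacency(adj)
  n <- nrow(adj)
  lens <- edge_lengths(adj)
  closeness <- numeric(n)
  betweenness <- numeric(n)
  for (s in seq_len(n)) {
    sp <- single_source_sp(lens, s)
    reach <- setdiff(which(is.finite(sp$dist)), s)
    closeness[s] <- if (length(reach)) length(reach) / sum(sp$dist[reach]) else 0
    delta <- numeric(n)
    for (w in rev(sp$order)) {
      coef <- (1 + delta[w]) / sp$sigma[w]
      for (u in sp$preds[[w]]) delta[u] <- delta[u] + sp$sigma[u] * coef
    }
    delta[s] <- 0
    betweenness <- betweenness + delta
  }
  # undirected: every pair was counted from both endpoints
  list(closeness = closeness, betweenness = betweenness / 2)
}

#' Degree / strength centrality
#'
#' Row sum of the adjacency: edge count on binary graphs, total edge weight
#' (node strength) on weighted graphs.
#'
#' @param adj Symmetric nonnegative adjacency matrix with zero diagonal
#'   (from [to_weighted_graph()] or [binarize()]).
#' @return Numeric vector, one value per node.
#' @export
centrality_degree <- function(adj) {
  validate_adjacency(adj)
  unname(rowSums(adj))
}

#' Closeness centrality
#'
#' Reciprocal of the mean shortest-path distance from a node to the nodes it
#' can reach: `|R(i)| / sum_{j in R(i)} d(i, j)`. Weighted graphs use edge
#' lengths `1/weight`. Isolated nodes get 0; on disconnected graphs only the
#' reachable set enters, preserving within-component ordering without
#' infinite distances.
#'
#' @inheritParams centrality_degree
#' @return Numeric vector, one value per node.
#' @export
centrality_closeness <- function(adj) {
  sp_centralities(adj)$closeness
}

#' Betweenness centrality
#'
#' Freeman betweenness with fractional counting:
#' `sum_{h < j, h != i != j} rho_hj(i) / rho_hj` where `rho_hj` counts
#' shortest paths between `h` and `j` and `rho_hj(i)` those passing through
#' `i`; endpoints excluded, values unnormalized. Computed by Brandes
#' accumulation (Dijkstra on lengths `1/weight`; unit lengths on binary
#' graphs).
#'
#' @inheritParams centrality_degree
#' @return Numeric vector, one value per node.
#' @export
centrality_betweenness <- function(adj) {
  sp_centralities(adj)$betweenness
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  current <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      current <- current + 1L
      queue <- s
      comp[s] <- current
      while (length(queue)) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        nb <- which(adj[v, ] > 0 & comp == 0L)
        comp[nb] <- current
        queue <- c(queue, nb)
      }
    }
  }
  unname(split(seq_len(n), comp))
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the adjacency matrix, rescaled to maximum entry 1.
#' Computed per connected component by shifted power iteration
#' (`A + 0.1 * max(strength) * I`, which shares eigenvectors with `A` and
#' breaks the +/- leading-eigenvalue tie of bipartite-spectrum graphs),
#' started from the uniform vector. On disconnected graphs the leading
#' eigenvector lives on the component with largest leading eigenvalue; other
#' components score exactly 0 (components tied within relative tolerance
#' 1e-8 are all retained, each rescaled to maximum 1). Convergence within a
#' component: sup-norm difference of normalized iterates below `tol`.
#'
#' @inheritParams centrality_degree
#' @param tol Convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap per component (default 10000);
#'   non-convergence raises a warning carrying the final sup-norm difference.
#' @return Numeric vector in \[0, 1\] with maximum 1 on non-empty graphs;
#'   all zeros on an empty graph.
#' @export
centrality_eigenvector <- function(adj, tol = 1e-10, max_iter = 10000) {
  validate_adjacency(adj)
  n <- nrow(adj)
  if (all(adj == 0)) return(numeric(n))
  comps <- graph_components(adj)
  lambdas <- numeric(length(comps))
  vectors <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    idx <- comps[[ci]]
    sub <- adj[idx, idx, drop = FALSE]
    if (all(sub == 0)) {
      vectors[[ci]] <- numeric(length(idx))
      next
    }
    shift <- 0.1 * max(rowSums(sub))
    x <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    diff <- Inf
    for (it in seq_len(max_iter)) {
      y <- as.vector(sub %*% x) + shift * x
      y <- y / sqrt(sum(y^2))
      diff <- max(abs(y - x))
      x <- y
      if (diff < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warn(sprintf(
        "eigenvector centrality did not converge in %d iterations (last change %.3g)",
        max_iter, diff))
    }
    x <- pmax(x, 0)
    lambdas[ci] <- sum(x * as.vector(sub %*% x)) / sum(x^2)
    vectors[[ci]] <- x / max(x)
  }
  lead <- max(lambdas)
  result <- numeric(n)
  for (ci in seq_along(comps)) {
    if (lambdas[ci] >= lead * (1 - 1e-8)) {
      result[comps[[ci]]] <- vectors[[ci]]
    }
  }
  result
}

#' Burt's constraint
#'
#' `c_i = sum_{j in N(i)} (p_ij + sum_{q != i,j} p_iq p_qj)^2` with
#' `p_ij = a_ij / sum_k a_ik`, node `i`'s proportional investment in `j`.
#' High values mark nodes whose connections are concentrated among mutually
#' connected neighbors; low values mark brokers. Nodes without neighbors get
#' 0, flagged in attribute `degenerate`.
#'
#' @inheritParams centrality_degree
#' @return Numeric vector with attribute `degenerate` (logical, TRUE for
#'   isolated nodes).
#' @export
centrality_constraint <- function(adj) {
  validate_adjacency(adj)
  strength <- rowSums(adj)
  isolated <- strength == 0
  p <- adj / ifelse(strength > 0, strength, 1)
  m <- p + p %*% p  # q = i and q = j terms vanish (zero diagonal of p)
  values <- rowSums(m^2 * (adj > 0))
  values[isolated] <- 0
  attr(values, "degenerate") <- isolated
  values
}

weighted_measures <- c("degree", "closeness", "betweenness", "eigenvector", "burt")
unweighted_measures <- c("degree", "closeness", "betweenness")

centrality_fun <- function(measure) {
  switch(measure,
    degree = centrality_degree,
    closeness = centrality_closeness,
    betweenness = centrality_betweenness,
    eigenvector = centrality_eigenvector,
    burt = centrality_constraint,
    abort(sprintf("unknown centrality measure '%s'", measure))
  )
}

#' Full centrality battery for one subject
#'
#' The canonical battery is 14 feature vectors: degree, closeness,
#' betweenness, eigenvector and Burt's constraint on the weighted graph, plus
#' degree, closeness and betweenness on each binary graph (eigenvector and
#' Burt's constraint are computed on weighted graphs only).
#'
#' @param weighted Weighted adjacency from [to_weighted_graph()].
#' @param binaries List of binary adjacencies from [binarize()] (each carrying
#'   its `cutoff` attribute).
#' @param measures Subset of
#'   `c("degree", "closeness", "betweenness", "eigenvector", "burt")`.
#' @return Tibble with columns `measure`, `graph_kind` (`"weighted"` /
#'   `"unweighted"`), `cutoff` (`NA` for weighted), `roi` (1-based index),
#'   `value`.
#' @export
centrality_profile <- function(weighted, binaries = list(),
                               measures = weighted_measures) {
  unknown <- setdiff(measures, weighted_measures)
  if (length(unknown)) {
    abort(sprintf("unknown centrality measure(s): %s", paste(unknown, collapse = ", ")))
  }
  n <- nrow(weighted)
  out <- list()
  for (meas in intersect(measures, weighted_measures)) {
    v <- centrality_fun(meas)(weighted)
    out[[length(out) + 1L]] <- tibble(measure = meas, graph_kind = "weighted",
                                      cutoff = NA_real_, roi = seq_len(n),
                                      value = as.numeric(v))
  }
  for (bg in binaries) {
    co <- attr(bg, "cutoff")
    if (is.null(co)) abort("binary graph lacks a `cutoff` attribute")
    for (meas in intersect(measures, unweighted_measures)) {
      v <- centrality_fun(meas)(bg)
      out[[length(out) + 1L]] <- tibble(measure = meas, graph_kind = "unweighted",
                                        cutoff = co, roi = seq_len(n),
                                        value = as.numeric(v))
    }
  }
  dplyr::bind_rows(out)
}

#' Centrality battery for a whole cohort
#'
#' Runs [correlation_matrix()], [to_weighted_graph()], [binarize()] and
#' [centrality_profile()] per subject and stacks the results in long format —
#' the cached feature store every classification task and scope draws from.
#'
#' @param cohort Cohort tibble ([simulate_cohort()] / [read_cohort()]).
#' @param cutoffs Binarization cut-offs (default `c(0.1, 0.15, 0.25)`).
#' @param measures Measure battery as in [centrality_profile()].
#' @return Long tibble: `subject_id`, `site`, `group`, `measure`,
#'   `graph_kind`, `cutoff`, `roi`, `value`.
#' @export
compute_centralities <- function(cohort, cutoffs = c(0.1, 0.15, 0.25),
                                 measures = weighted_measures) {
  purrr::pmap(
    list(cohort$subject_id, cohort$site, cohort$group, cohort$timeseries),
    function(id, site, group, ts) {
      cm <- correlation_matrix(ts)
      wg <- to_weighted_graph(cm)
      bgs <- lapply(cutoffs, function(co) binarize(cm, co))
      prof <- centrality_profile(wg, bgs, measures)
      dplyr::mutate(prof, subject_id = id, site = site, group = group,
                    .before = 1)
    }
  ) |>
    dplyr::bind_rows()
}
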