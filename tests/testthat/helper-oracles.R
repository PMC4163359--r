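# Brute-force reference implementations for the centrality measures,
# deliberately independent of the package's algorithms: Floyd-Warshall
# distances, pair-splitting betweenness, dense eigendecomposition, and a
# direct triple loop for Burt's constraint.

oracle_lengths <- function(adj) {
  lens <- 1 / adj
  lens[adj <= 0] <- Inf
  diag(lens) <- 0
  lens
}

# all-pairs shortest-path distances by Floyd-Warshall
oracle_distances <- function(adj) {
  d <- oracle_lengths(adj)
  n <- nrow(d)
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, via)
  }
  d
}

# shortest-path counts sigma[s, v] from the distance matrix: process nodes in
# increasing distance from s, summing counts over tight incoming edges
oracle_sigma <- function(adj, D) {
  n <- nrow(adj)
  lens <- oracle_lengths(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      for (u in which(adj[, v] > 0)) {
        tol <- 1e-9 * max(1, abs(D[s, v]))
        if (abs(D[s, u] + lens[u, v] - D[s, v]) <= tol) {
          sigma[s, v] <- sigma[s, v] + sigma[s, u]
        }
      }
    }
  }
  sigma
}

# Freeman betweenness via the pair-splitting identity: i lies on a shortest
# h-j path iff d(h,i) + d(i,j) = d(h,j), contributing sigma_hi*sigma_ij/sigma_hj
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  sigma <- oracle_sigma(adj, D)
  bt <- numeric(n)
  for (i in seq_len(n)) {
    for (h in seq_len(n)) {
      for (j in seq_len(n)) {
        if (h >= j || h == i || j == i || !is.finite(D[h, j])) next
        tol <- 1e-9 * max(1, abs(D[h, j]))
        if (abs(D[h, i] + D[i, j] - D[h, j]) <= tol) {
          bt[i] <- bt[i] + sigma[h, i] * sigma[i, j] / sigma[h, j]
        }
      }
    }
  }
  bt
}

oracle_closeness <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) length(d) / sum(d) else 0
  }, numeric(1))
}

# leading eigenvector by dense eigendecomposition, max-normalized; NULL when
# the leading eigenvalue is (nearly) multiple and the limit is not unique
oracle_eigenvector <- function(adj, gap_tol = 1e-6) {
  if (all(adj == 0)) return(numeric(nrow(adj)))
  e <- eigen(adj, symmetric = TRUE)
  if (nrow(adj) > 1 && e$values[1] - e$values[2] < gap_tol) return(NULL)
  v <- abs(e$vectors[, 1])
  v / max(v)
}

oracle_constraint <- function(adj) {
  n <- nrow(adj)
  strength <- rowSums(adj)
  p <- function(i, j) if (strength[i] > 0) adj[i, j] / strength[i] else 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (strength[i] == 0) next
    total <- 0
    for (j in which(adj[i, ] > 0)) {
      indirect <- 0
      for (q in seq_len(n)) {
        if (q != i && q != j) indirect <- indirect + p(i, q) * p(q, j)
      }
      total <- total + (p(i, j) + indirect)^2
    }
    out[i] <- total
  }
  out
}

# random undirected test graphs: Erdos-Renyi, optionally with uniform weights
random_adjacency <- function(n, p = 0.4, weighted = FALSE) {
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  on <- up[runif(length(up)) < p]
  adj[on] <- if (weighted) runif(length(on), 0.1, 1) else 1
  adj <- adj + t(adj)
  adj
}

# small named graphs used in the hand-derived examples
graph_star <- function(k = 4) {
  adj <- matrix(0, k + 1, k + 1)
  adj[1, 2:(k + 1)] <- 1
  adj + t(adj)
}

graph_cycle <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) adj[i, i %% n + 1] <- 1
  pmax(adj, t(adj))
}

graph_complete <- function(n) {
  adj <- matrix(1, n, n)
  diag(adj) <- 0
  adj
}

graph_path <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- 1
  adj + t(adj)
}
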