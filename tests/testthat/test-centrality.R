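# Hand-derived values on named graphs, then equivalence against brute-force
# oracles and igraph on random graphs, then structural properties.

test_that("degree and strength match hand sums", {
  star <- graph_star(4)
  expect_equal(centrality_degree(star), c(4, 1, 1, 1, 1))
  expect_equal(centrality_degree(matrix(0, 3, 3)), rep(0, 3))

  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 0.5
  tri[1, 3] <- tri[3, 1] <- 0.3
  tri[2, 3] <- tri[3, 2] <- 0.2
  expect_equal(centrality_degree(tri), c(0.8, 0.7, 0.5))
})

test_that("closeness follows the reachable-set mean-distance convention", {
  expect_equal(centrality_closeness(graph_path(3)), c(2 / 3, 1, 2 / 3))
  expect_equal(centrality_closeness(graph_complete(5)), rep(1, 5))

  two_comp <- matrix(0, 3, 3)
  two_comp[1, 2] <- two_comp[2, 1] <- 1
  expect_equal(centrality_closeness(two_comp), c(1, 1, 0))
})

test_that("betweenness matches exhaustive path reasoning on named graphs", {
  expect_equal(centrality_betweenness(graph_star(4)), c(6, 0, 0, 0, 0))
  expect_equal(centrality_betweenness(graph_cycle(4)), rep(0.5, 4))
  expect_equal(centrality_betweenness(graph_complete(6)), rep(0, 6))
})

test_that("eigenvector centrality solves the named leading eigenproblems", {
  # cycle: uniform by symmetry
  expect_equal(centrality_eigenvector(graph_cycle(5)), rep(1, 5), tolerance = 1e-8)
  expect_equal(centrality_eigenvector(graph_cycle(4)), rep(1, 4), tolerance = 1e-8)

  # star K_{1,4}: leading eigenpair l = 2, center twice each leaf
  expect_equal(centrality_eigenvector(graph_star(4)), c(1, .5, .5, .5, .5),
               tolerance = 1e-8)

  # triangle with a separate edge: support concentrates on the triangle
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 3] <- adj[1, 3] <- 1
  adj[4, 5] <- 1
  adj <- pmax(adj, t(adj))
  v <- centrality_eigenvector(adj)
  expect_equal(v[1:3], rep(1, 3), tolerance = 1e-6)
  expect_lt(max(v[4:5]), 1e-6)

  expect_equal(centrality_eigenvector(matrix(0, 4, 4)), rep(0, 4))
})

test_that("Burt's constraint reproduces the hand-evaluated formula", {
  star <- graph_star(4)
  cval <- centrality_constraint(star)
  expect_equal(cval[1], 0.25, ignore_attr = TRUE)       # 4 * (1/4)^2
  expect_equal(unname(cval[2:5]), rep(1, 4))            # single neighbor, p = 1

  expect_equal(unname(centrality_constraint(graph_complete(3))),
               rep(1.125, 3), ignore_attr = TRUE)                           # 2 * (1/2 + 1/4)^2

  iso <- matrix(0, 3, 3)
  iso[1, 2] <- iso[2, 1] <- 1
  cv <- centrality_constraint(iso)
  expect_equal(unname(cv[3]), 0)
  expect_equal(attr(cv, "degenerate"), c(FALSE, FALSE, TRUE))
})

test_that("all measures agree with brute-force oracles on random graphs", {
  set.seed(99)
  n_checked <- 0
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, p = runif(1, 0.2, 0.7), weighted = rep %% 2 == 0)
    expect_equal(centrality_degree(adj), rowSums(adj), ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_equal(centrality_closeness(adj), oracle_closeness(adj), tolerance = 1e-8)
    expect_equal(centrality_betweenness(adj), oracle_betweenness(adj),
                 tolerance = 1e-8)
    expect_equal(unname(centrality_constraint(adj)), oracle_constraint(adj),
                 tolerance = 1e-8, ignore_attr = TRUE)
    ev_ref <- oracle_eigenvector(adj)
    if (!is.null(ev_ref) && length(ev_ref)) {
      expect_equal(centrality_eigenvector(adj), ev_ref, tolerance = 1e-7)
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 60)
})

test_that("measures agree with igraph as an independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    adj <- random_adjacency(n, p = 0.5, weighted = TRUE)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    w <- igraph::E(g)$weight
    expect_equal(centrality_degree(adj), unname(igraph::strength(g)),
                 tolerance = 1e-10)
    expect_equal(centrality_betweenness(adj),
                 unname(igraph::betweenness(g, weights = 1 / w)),
                 tolerance = 1e-8)
    # igraph reports NaN for isolated nodes where we define 0
    ig_con <- unname(igraph::constraint(g))
    ig_con[is.nan(ig_con)] <- 0
    expect_equal(unname(centrality_constraint(adj)), ig_con, tolerance = 1e-8,
                 ignore_attr = TRUE)
    if (igraph::is_connected(g)) {
      ours <- centrality_eigenvector(adj)
      theirs <- igraph::eigen_centrality(g, weights = w)$vector
      expect_equal(ours, unname(theirs), tolerance = 1e-6)
      # closeness: igraph reports 1 / sum(d); ours is (n-1) / sum(d)
      expect_equal(centrality_closeness(adj),
                   unname(igraph::closeness(g, weights = 1 / w)) * (n - 1),
                   tolerance = 1e-8)
    }
  }
})

test_that("relabeling nodes permutes every centrality vector identically", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 9
    adj <- random_adjacency(n, p = 0.5, weighted = TRUE)
    perm <- sample(n)
    padj <- adj[perm, perm]
    for (f in list(centrality_degree, centrality_closeness,
                   centrality_betweenness, centrality_eigenvector,
                   centrality_constraint)) {
      expect_equal(unname(f(padj)), unname(f(adj))[perm], tolerance = 1e-7,
                   ignore_attr = TRUE)
    }
  }
})

test_that("global weight rescaling behaves as the measure definitions imply", {
  set.seed(8)
  adj <- random_adjacency(10, p = 0.5, weighted = TRUE)
  c_mult <- 3.7
  expect_equal(centrality_degree(c_mult * adj), c_mult * centrality_degree(adj))
  expect_equal(centrality_eigenvector(c_mult * adj), centrality_eigenvector(adj),
               tolerance = 1e-8)
  expect_equal(unname(centrality_constraint(c_mult * adj)),
               unname(centrality_constraint(adj)), tolerance = 1e-10)
  # shortest-path structure is scale-free: rankings preserved
  expect_equal(order(centrality_betweenness(c_mult * adj)),
               order(centrality_betweenness(adj)))
  expect_equal(order(centrality_closeness(c_mult * adj)),
               order(centrality_closeness(adj)))
})

test_that("unweighted degree is non-increasing in the cut-off", {
  set.seed(9)
  ts <- matrix(rnorm(50 * 15), 50, 15)
  cm <- correlation_matrix(ts)
  d10 <- centrality_degree(binarize(cm, 0.1))
  d15 <- centrality_degree(binarize(cm, 0.15))
  d25 <- centrality_degree(binarize(cm, 0.25))
  expect_true(all(d15 <= d10))
  expect_true(all(d25 <= d15))
})

test_that("the profile emits the full 14-vector battery and handles edge cases", {
  set.seed(10)
  ts <- matrix(rnorm(60 * 8), 60, 8)
  cm <- correlation_matrix(ts)
  wg <- to_weighted_graph(cm)
  bgs <- lapply(c(0.1, 0.15, 0.25), function(co) binarize(cm, co))

  prof <- centrality_profile(wg, bgs)
  combos <- dplyr::distinct(prof, measure, graph_kind, cutoff)
  expect_equal(nrow(combos), 14)
  expect_equal(nrow(prof), 14 * 8)

  one <- centrality_profile(wg, list(), measures = "degree")
  expect_equal(nrow(dplyr::distinct(one, measure, graph_kind)), 1)

  # empty graph: all-zero vectors, no error
  empty <- centrality_profile(matrix(0, 4, 4),
                              list(structure(matrix(0, 4, 4), cutoff = 0.1)))
  expect_true(all(empty$value == 0))

  expect_error(centrality_profile(wg, measures = "pagerank"), "unknown")
})
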