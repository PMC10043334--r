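# The metric battery against brute-force twins and canonical graphs.

test_that("canonical graphs give textbook metric values", {
  K24 <- matrix(1, 24, 24); diag(K24) <- 0
  expect_equal(global_degree(K24, directed = TRUE), 552)  # R*(R-1)
  expect_equal(global_degree(matrix(0, 4, 4), directed = TRUE), 0)

  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(global_strength(K5, directed = FALSE), 4)
  expect_equal(global_strength(K5 / 2, directed = FALSE), 2)  # linearity
  expect_equal(unname(clustering_and_transitivity(K5, directed = FALSE)),
               c(1, 1))
  expect_equal(unname(efficiency_and_path_length(K5, directed = FALSE)),
               c(1, 1))
  expect_equal(flow_coefficient(K5, directed = FALSE), 0)
  expect_equal(graph_modularity(K5, seed = 1, directed = FALSE), 0,
               tolerance = 1e-12)

  ring5 <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; ring5[i, j] <- ring5[j, i] <- 1 }
  expect_equal(unname(clustering_and_transitivity(ring5, directed = FALSE)),
               c(0, 0))

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(unname(efficiency_and_path_length(path3, directed = FALSE)),
               c(5 / 6, 4 / 3))

  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star[2:6, 1] <- 1
  expect_equal(assortativity_in_out(star, directed = FALSE), -1)
  expect_equal(flow_coefficient(star, directed = FALSE), 1 / 6)

  cyc3 <- matrix(0, 3, 3); cyc3[1, 2] <- cyc3[2, 3] <- cyc3[3, 1] <- 1
  expect_true(is.na(assortativity_in_out(cyc3, directed = TRUE)))

  cliques <- matrix(0, 8, 8)
  cliques[1:4, 1:4] <- 1; cliques[5:8, 5:8] <- 1; diag(cliques) <- 0
  expect_equal(graph_modularity(cliques, seed = 2, directed = FALSE), 0.5)
})

test_that("every metric matches its brute-force twin on random graphs", {
  n_graphs <- 100
  worst_mod_gap <- 0
  for (g in seq_len(n_graphs)) {
    n <- 5 + (g %% 6)           # sizes 5..10
    p <- 0.25 + 0.5 * ((g %% 4) / 4)
    directed <- g %% 2 == 0
    A <- if (directed) rand_directed_graph(n, p, seed = 5000 + g)
         else rand_undirected_graph(n, p, seed = 5000 + g)
    W <- A * rand_weighted_graph(n, 1, seed = 6000 + g)
    if (!directed) W[lower.tri(W)] <- t(W)[lower.tri(W)]

    expect_equal(global_degree(A, directed), oracle_degree(A, directed))
    expect_equal(global_strength(W, directed), oracle_strength(W, directed),
                 tolerance = 1e-12)
    ct <- clustering_and_transitivity(A, directed)
    ct_or <- if (directed) oracle_clust_trans_dir(A)
             else oracle_clust_trans_undir(A)
    expect_equal(unname(ct), unname(ct_or), tolerance = 1e-10)
    expect_equal(unname(efficiency_and_path_length(A, directed)),
                 unname(oracle_eff_cpl(A)))
    expect_equal(assortativity_in_out(A, directed),
                 oracle_assort(A, directed), tolerance = 1e-10)
    expect_equal(flow_coefficient(A, directed), oracle_flow(A),
                 tolerance = 1e-12)
    if (n <= 8 && sum(A) > 0) {
      q_heur <- graph_modularity(A, seed = g, directed = directed)
      q_true <- oracle_modularity_exhaustive(A)
      expect_lte(q_heur, q_true + 1e-10)
      worst_mod_gap <- max(worst_mod_gap, q_true - q_heur)
    }
  }
  expect_lte(worst_mod_gap, 0.02)
})

test_that("undirected metrics agree with igraph on random graphs", {
  for (s in 1:10) {
    A <- rand_undirected_graph(9, 0.4, seed = 7000 + s)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(clustering_and_transitivity(A, FALSE)[["transitivity"]],
                 igraph::transitivity(g, type = "global"), tolerance = 1e-12)
    D <- igraph::distances(g)
    off <- row(D) != col(D)
    expect_equal(unname(efficiency_and_path_length(A, FALSE)),
                 c(mean(ifelse(is.finite(D[off]), 1 / D[off], 0)),
                   mean(D[off][is.finite(D[off])])))
    # our greedy optimum is at least as good as igraph's fast_greedy
    q_ig <- igraph::modularity(g, igraph::membership(
      igraph::cluster_fast_greedy(g)))
    expect_gte(graph_modularity(A, seed = s, directed = FALSE),
               q_ig - 1e-10)
  }
})

test_that("metrics are invariant under node relabeling", {
  A <- rand_directed_graph(8, 0.4, seed = 71)
  set.seed(72)
  perm <- sample(8)
  B <- A[perm, perm]
  expect_equal(global_degree(A, TRUE), global_degree(B, TRUE))
  expect_equal(unname(clustering_and_transitivity(A, TRUE)),
               unname(clustering_and_transitivity(B, TRUE)))
  expect_equal(unname(efficiency_and_path_length(A, TRUE)),
               unname(efficiency_and_path_length(B, TRUE)))
  expect_equal(assortativity_in_out(A, TRUE), assortativity_in_out(B, TRUE))
  expect_equal(flow_coefficient(A, TRUE), flow_coefficient(B, TRUE))
  expect_equal(graph_modularity(A, seed = 1), graph_modularity(B, seed = 1),
               tolerance = 1e-10)
})

test_that("reciprocated directed graphs collapse to their undirected values", {
  A <- rand_undirected_graph(9, 0.4, seed = 81)  # symmetric 0/1 matrix
  dir_ct <- clustering_and_transitivity(A, directed = TRUE)
  und_ct <- clustering_and_transitivity(A, directed = FALSE)
  expect_equal(unname(dir_ct), unname(und_ct), tolerance = 1e-12)
  expect_equal(unname(efficiency_and_path_length(A, directed = TRUE)),
               unname(efficiency_and_path_length(A, directed = FALSE)))
})

test_that("random-graph degree matches its binomial expectation", {
  degs <- vapply(seq_len(200), function(s) {
    global_degree(rand_directed_graph(24, 0.5, seed = 9000 + s),
                  directed = TRUE)
  }, numeric(1))
  expect_equal(mean(degs), 0.5 * 24 * 23, tolerance = 0.02)
})

test_that("small-worldness separates lattices from their random nulls", {
  # a random directed graph against its own null ensemble: sigma near 1
  sig_null <- vapply(seq_len(20), function(s) {
    A <- rand_directed_graph(16, 0.3, seed = 400 + s)
    small_worldness(A, n_null = 20, n_rewire = 10, seed = s, directed = TRUE)
  }, numeric(1))
  expect_gt(mean(sig_null), 0.8)
  expect_lt(mean(sig_null), 1.2)

  # Watts-Strogatz ring: strongly small-world
  sig_ws <- vapply(seq_len(20), function(s) {
    A <- ws_ring(30, 4, 0.1, seed = 500 + s)
    small_worldness(A, n_null = 20, n_rewire = 10, seed = s,
                    directed = FALSE)
  }, numeric(1))
  expect_gte(mean(sig_ws > 1), 0.95)

  A <- ws_ring(30, 4, 0.1, seed = 501)
  s1 <- small_worldness(A, n_null = 15, n_rewire = 10, seed = 3,
                        directed = FALSE)
  s2 <- small_worldness(A, n_null = 15, n_rewire = 10, seed = 3,
                        directed = FALSE)
  expect_identical(s1, s2)
  expect_error(small_worldness(A, n_null = 5), "n_null")
})

test_that("rewiring preserves in- and out-degree sequences", {
  A <- rand_directed_graph(12, 0.3, seed = 61)
  B <- with(list(), {
    set.seed(62)
    gcconnect:::rewire_preserving_degree(A, directed = TRUE, n_swaps = 200)
  })
  expect_equal(rowSums(B), rowSums(A))
  expect_equal(colSums(B), colSums(A))
  expect_false(identical(A, B))

  U <- rand_undirected_graph(12, 0.3, seed = 63)
  V <- with(list(), {
    set.seed(64)
    gcconnect:::rewire_preserving_degree(U, directed = FALSE, n_swaps = 200)
  })
  expect_true(isSymmetric(V))
  expect_equal(rowSums(V), rowSums(U))
})

test_that("metric_vector composes the individual metrics and flags undefined ones", {
  g <- rand_directed_graph(7, 0.45, seed = 91)
  mv <- metric_vector(g, n_null = 15, seed = 5, directed = TRUE)
  expect_named(mv, c("degree", "strength", "clustering_coefficient",
                     "transitivity", "modularity", "global_efficiency",
                     "characteristic_path_length", "assortativity_in_out",
                     "small_worldness", "flow_coefficient"))
  expect_equal(mv[["degree"]], global_degree(g, TRUE))
  expect_equal(mv[["flow_coefficient"]], flow_coefficient(g, TRUE))
  expect_equal(mv[["modularity"]], graph_modularity(g, seed = 5))
  expect_true(all(is.finite(mv)))

  cyc3 <- matrix(0, 3, 3); cyc3[1, 2] <- cyc3[2, 3] <- cyc3[3, 1] <- 1
  mv3 <- metric_vector(cyc3, n_null = 10, seed = 1, directed = TRUE)
  expect_true(is.na(mv3[["assortativity_in_out"]]))  # regular graph

  tab <- cohort_metric_table(list(P1 = g, P2 = g), n_null = 10, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_true("characteristic_path_length" %in% names(tab))
})
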