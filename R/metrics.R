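# Ten global graph metrics with directed (effective connectivity) and
# undirected (functional connectivity) variants. Binary metrics consume the
# significance mask; strength consumes |weights|. Conventions follow the
# ones common in brain-network analysis: directed clustering counts all
# triangle orientations with a reciprocal-edge correction in the
# denominator; unreachable pairs are excluded from path length and
# contribute 0 to efficiency; nodes with fewer than two neighbours
# contribute 0 to mean clustering and flow.

# coerce input to a connectivity_graph (matrices: mask = nonzero entries)
as_conn_graph <- function(x, directed = NULL) {
  if (inherits(x, "connectivity_graph")) return(x)
  if (is.matrix(x)) {
    if (is.null(directed)) directed <- !isSymmetric(unname(x))
    labels <- colnames(x) %||% paste0("ROI", seq_len(ncol(x)))
    w <- x
    diag(w) <- 0
    return(make_graph(labels, w, mask = w != 0, directed = directed,
                      subclass = if (directed) "ec_graph" else "fc_graph"))
  }
  stop("expected a connectivity_graph or an adjacency matrix")
}

bin_adj <- function(g) {
  A <- (g$mask) * 1
  diag(A) <- 0
  if (!g$directed) A <- pmax(A, t(A))
  A
}

#' Global degree: total edge count
#'
#' Number of edges in the significance mask; each directed edge counted
#' once, each undirected edge counted once.
#'
#' @param graph A `connectivity_graph` or adjacency matrix.
#' @param directed Used only when `graph` is a plain matrix.
#' @return Edge count (non-negative real).
#' @export
global_degree <- function(graph, directed = NULL) {
  g <- as_conn_graph(graph, directed)
  A <- bin_adj(g)
  if (g$directed) sum(A) else sum(A) / 2
}

#' Global strength: mean nodal strength of absolute weights
#'
#' Nodal strength is the sum of |weights| incident on a node (the mean of
#' in- and out-strength for directed graphs); the global value is the mean
#' over nodes.
#'
#' @inheritParams global_degree
#' @return Mean nodal strength.
#' @export
global_strength <- function(graph, directed = NULL) {
  g <- as_conn_graph(graph, directed)
  W <- abs(g$weights)
  diag(W) <- 0
  s <- if (g$directed) (rowSums(W) + colSums(W)) / 2 else rowSums(W)
  mean(s)
}

#' Clustering coefficient and transitivity
#'
#' Binary triangle-density measures. Undirected: mean nodal triangle
#' fraction and the global triangles-to-triplets ratio. Directed: the
#' generalization counting all triangle orientations,
#' `C_i = ((A + A')^3)_ii / (2 * (d_tot (d_tot - 1) - 2 d_recip))`, with
#' transitivity the ratio of the summed numerators and denominators.
#' Nodes with fewer than two neighbours contribute 0 to the mean.
#'
#' @inheritParams global_degree
#' @return Named numeric vector `c(clustering, transitivity)`.
#' @export
clustering_and_transitivity <- function(graph, directed = NULL) {
  g <- as_conn_graph(graph, directed)
  A <- bin_adj(g)
  if (g$directed) {
    S <- A + t(A)
    tri <- diag(S %*% S %*% S) / 2
    d_tot <- rowSums(A) + colSums(A)
    d_bi <- diag(A %*% A)
    denom <- d_tot * (d_tot - 1) - 2 * d_bi
  } else {
    tri <- diag(A %*% A %*% A) / 2  # triangles through each node
    k <- rowSums(A)
    denom <- k * (k - 1) / 2
  }
  Ci <- ifelse(denom > 0, tri / denom, 0)
  clustering <- mean(Ci)
  transitivity <- if (sum(denom) > 0) sum(tri) / sum(denom) else 0
  c(clustering = clustering, transitivity = transitivity)
}

# Newman modularity of a given partition; for undirected graphs A is
# symmetric and this reduces to the standard k_i k_j / 2m null model, for
# directed graphs it is the in/out-degree (Leicht-Newman) null model.
modularity_q <- function(A, membership, directed = TRUE) {
  m <- sum(A)
  if (m == 0) return(0)
  kout <- rowSums(A); kin <- colSums(A)
  same <- outer(membership, membership, `==`)
  sum((A / m - outer(kout, kin) / m^2) * same)
}

#' Maximized Newman modularity
#'
#' Greedy multi-restart community detection (label moving with a final
#' community-merge pass), reporting the best modularity Q over `n_restarts`
#' seeded restarts. Directed graphs use the in/out-degree null model.
#'
#' @inheritParams global_degree
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of restarts (default 20).
#' @return Best Q found (in \[-0.5, 1\]).
#' @export
graph_modularity <- function(graph, seed = 1L, n_restarts = 20L,
                             directed = NULL) {
  g <- as_conn_graph(graph, directed)
  A <- bin_adj(g)
  n <- nrow(A)
  if (sum(A) == 0) stop("modularity is undefined for an edgeless graph")
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0 | A[, i] > 0))

  best_q <- -Inf
  with_seed(mix_seed(seed, 40127L), {
    for (r in seq_len(n_restarts)) {
      # restart 1 from singletons, later restarts from random coarser
      # partitions so different basins of attraction are explored
      memb <- if (r == 1) seq_len(n) else {
        sample.int(sample.int(n, 1), n, replace = TRUE)
      }
      q <- modularity_q(A, memb, g$directed)
      repeat {   # alternate node moves and community merges to a fixed point
        pass_improved <- FALSE
        repeat {
          improved <- FALSE
          for (i in sample(n)) {
            # candidate targets: any existing community or a fresh singleton
            cand <- unique(c(memb[nbrs[[i]]], memb, max(memb) + 1L))
            best_c <- memb[i]; best_dq <- 0
            for (cc in cand) {
              if (cc == memb[i]) next
              memb2 <- memb; memb2[i] <- cc
              dq <- modularity_q(A, memb2, g$directed) - q
              if (dq > best_dq + 1e-12) { best_dq <- dq; best_c <- cc }
            }
            if (best_c != memb[i]) { memb[i] <- best_c; q <- q + best_dq
              improved <- TRUE; pass_improved <- TRUE }
          }
          if (!improved) break
        }
        repeat {  # agglomerate communities while it helps
          comms <- unique(memb)
          if (length(comms) < 2) break
          best_dq <- 0; best_pair <- NULL
          for (a in seq_along(comms)) for (b in seq_len(a - 1)) {
            memb2 <- memb; memb2[memb2 == comms[a]] <- comms[b]
            dq <- modularity_q(A, memb2, g$directed) - q
            if (dq > best_dq + 1e-12) { best_dq <- dq
              best_pair <- c(comms[a], comms[b]) }
          }
          if (is.null(best_pair)) break
          memb[memb == best_pair[1]] <- best_pair[2]
          q <- q + best_dq
          pass_improved <- TRUE
        }
        if (!pass_improved) break
      }
      if (q > best_q) best_q <- q
    }
  })
  best_q
}

# all-pairs shortest binary path lengths (BFS per source), Inf if unreachable
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  adj <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

#' Global efficiency and characteristic path length
#'
#' Binary shortest paths over the significance mask. Efficiency is the mean
#' over ordered node pairs of the inverse shortest path length (0 for
#' unreachable pairs); characteristic path length is the mean shortest path
#' over reachable ordered pairs.
#'
#' @inheritParams global_degree
#' @return Named numeric vector `c(global_efficiency,
#'   characteristic_path_length)` (path length `NA` when no pair is
#'   reachable).
#' @export
efficiency_and_path_length <- function(graph, directed = NULL) {
  g <- as_conn_graph(graph, directed)
  A <- bin_adj(g)
  D <- bfs_distances(A)
  off <- row(D) != col(D)
  d <- D[off]
  eff <- mean(ifelse(is.finite(d), 1 / d, 0))
  reach <- d[is.finite(d)]
  cpl <- if (length(reach)) mean(reach) else NA_real_
  c(global_efficiency = eff, characteristic_path_length = cpl)
}

#' In-out degree assortativity
#'
#' Directed graphs: Pearson correlation, over directed edges, of the source
#' node's in-degree with the target node's out-degree. Undirected graphs:
#' the standard degree-degree assortativity (each edge contributing both
#' orientations). Undefined (returns `NA`) when either endpoint degree has
#' zero variance, as in regular graphs.
#'
#' @inheritParams global_degree
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
assortativity_in_out <- function(graph, directed = NULL) {
  g <- as_conn_graph(graph, directed)
  A <- bin_adj(g)
  e <- which(A > 0, arr.ind = TRUE)
  if (nrow(e) < 2) return(NA_real_)
  if (g$directed) {
    x <- colSums(A)[e[, 1]]  # in-degree of source
    y <- rowSums(A)[e[, 2]]  # out-degree of target
  } else {
    k <- rowSums(A)
    x <- k[e[, 1]]
    y <- k[e[, 2]]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# degree-preserving rewiring by double edge swaps (directed: preserves in-
# and out-degrees; undirected: preserves degrees); uses the current RNG
rewire_preserving_degree <- function(A, directed, n_swaps,
                                     max_tries = 50 * n_swaps + 100) {
  n <- nrow(A)
  done <- 0; tries <- 0
  el <- which(A > 0, arr.ind = TRUE)
  if (!directed) el <- el[el[, 1] < el[, 2], , drop = FALSE]
  m <- nrow(el)
  if (m < 2) return(A)
  while (done < n_swaps && tries < max_tries) {
    tries <- tries + 1
    pick <- sample.int(m, 2)
    a <- el[pick[1], 1]; b <- el[pick[1], 2]
    c_ <- el[pick[2], 1]; d <- el[pick[2], 2]
    if (directed) {
      # (a->b, c->d) becomes (a->d, c->b)
      if (a == d || c_ == b || a == c_ || b == d) next
      if (A[a, d] > 0 || A[c_, b] > 0) next
      A[a, b] <- 0; A[c_, d] <- 0; A[a, d] <- 1; A[c_, b] <- 1
      el[pick[1], ] <- c(a, d); el[pick[2], ] <- c(c_, b)
    } else {
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (length(unique(c(a, b, c_, d))) < 4) next
      if (A[a, d] > 0 || A[c_, b] > 0) next
      A[a, b] <- 0; A[b, a] <- 0; A[c_, d] <- 0; A[d, c_] <- 0
      A[a, d] <- 1; A[d, a] <- 1; A[c_, b] <- 1; A[b, c_] <- 1
      el[pick[1], ] <- sort(c(a, d)); el[pick[2], ] <- sort(c(c_, b))
    }
    done <- done + 1
  }
  if (done == 0 && n_swaps > 0 && m >= 2) {
    stop("degree-preserving rewiring failed: pathological degree sequence")
  }
  A
}

#' Small-worldness against a degree-preserving null ensemble
#'
#' `sigma = (C / C_null) / (L / L_null)` where C is mean clustering, L the
#' characteristic path length, and the null values are means over `n_null`
#' rewired graphs obtained by `n_rewire` degree-preserving edge swaps per
#' edge. Values above 1 indicate small-world organization (clustered yet
#' short-pathed).
#'
#' @inheritParams global_degree
#' @param n_null Number of null graphs (>= 10).
#' @param n_rewire Swaps per edge for each null graph.
#' @param seed Integer seed for the null ensemble.
#' @return Small-worldness sigma.
#' @export
small_worldness <- function(graph, n_null = 100L, n_rewire = 10L, seed = 1L,
                            directed = NULL) {
  if (n_null < 10) stop("n_null must be at least 10")
  g <- as_conn_graph(graph, directed)
  A <- bin_adj(g)
  ct <- clustering_and_transitivity(g)
  el <- efficiency_and_path_length(g)
  C <- ct[["clustering"]]; L <- el[["characteristic_path_length"]]
  n_edges <- if (g$directed) sum(A) else sum(A) / 2
  Cn <- Ln <- numeric(n_null)
  with_seed(mix_seed(seed, 88011L), {
    for (b in seq_len(n_null)) {
      An <- rewire_preserving_degree(A, g$directed, n_swaps = n_rewire * n_edges)
      gn <- as_conn_graph(An, directed = g$directed)
      Cn[b] <- clustering_and_transitivity(gn)[["clustering"]]
      Ln[b] <- efficiency_and_path_length(gn)[["characteristic_path_length"]]
    }
  })
  (C / mean(Cn)) / (L / mean(Ln))
}

#' Flow coefficient
#'
#' For each node v, the fraction of ordered neighbour pairs (i, j) with no
#' direct edge i -> j for which the length-2 path i -> v -> j exists;
#' neighbours are nodes connected to v in either direction. Nodes with
#' fewer than two neighbours, or with no unconnected neighbour pair,
#' contribute 0. The global value is the mean over nodes.
#'
#' @inheritParams global_degree
#' @return Mean nodal flow coefficient in \[0, 1\].
#' @export
flow_coefficient <- function(graph, directed = NULL) {
  g <- as_conn_graph(graph, directed)
  A <- bin_adj(g)
  n <- nrow(A)
  fc <- numeric(n)
  for (v in seq_len(n)) {
    nbrs <- which(A[v, ] > 0 | A[, v] > 0)
    nbrs <- setdiff(nbrs, v)
    if (length(nbrs) < 2) next
    num <- 0; den <- 0
    for (i in nbrs) for (j in nbrs) {
      if (i == j || A[i, j] > 0) next
      den <- den + 1
      if (A[i, v] > 0 && A[v, j] > 0) num <- num + 1
    }
    fc[v] <- if (den > 0) num / den else 0
  }
  mean(fc)
}

#' Compute the full ten-metric vector for one graph
#'
#' Degree, strength, clustering coefficient, transitivity, modularity,
#' global efficiency, characteristic path length, in-out assortativity,
#' small-worldness and flow coefficient, using the directed or undirected
#' variant according to the graph type. Binary metrics consume the
#' significance mask; strength consumes |weights|. Metrics that are
#' undefined for the graph (e.g. assortativity of a regular graph) are
#' reported as `NA`, never silently zeroed.
#'
#' @inheritParams global_degree
#' @param n_null,n_rewire,seed Null-model settings for [small_worldness()].
#' @param modularity_restarts Restarts for [graph_modularity()].
#' @return Named numeric vector of the ten metrics.
#' @export
metric_vector <- function(graph, n_null = 100L, n_rewire = 10L, seed = 1L,
                          modularity_restarts = 20L, directed = NULL) {
  g <- as_conn_graph(graph, directed)
  ct <- clustering_and_transitivity(g)
  el <- efficiency_and_path_length(g)
  mod <- tryCatch(graph_modularity(g, seed = seed,
                                   n_restarts = modularity_restarts),
                  error = function(e) NA_real_)
  sw <- tryCatch(small_worldness(g, n_null = n_null, n_rewire = n_rewire,
                                 seed = seed),
                 error = function(e) NA_real_)
  c(degree = global_degree(g),
    strength = global_strength(g),
    clustering_coefficient = ct[["clustering"]],
    transitivity = ct[["transitivity"]],
    modularity = mod,
    global_efficiency = el[["global_efficiency"]],
    characteristic_path_length = el[["characteristic_path_length"]],
    assortativity_in_out = assortativity_in_out(g),
    small_worldness = sw,
    flow_coefficient = flow_coefficient(g))
}

#' Metric table for a list of participant graphs
#'
#' @param graphs Named list of `connectivity_graph` objects (names become
#'   participant ids).
#' @inheritParams metric_vector
#' @return `data.frame` with `participant_id` and one column per metric.
#' @export
cohort_metric_table <- function(graphs, n_null = 100L, n_rewire = 10L,
                                seed = 1L, modularity_restarts = 20L) {
  stopifnot(length(graphs) > 0)
  ids <- names(graphs) %||% as.character(seq_along(graphs))
  rows <- lapply(seq_along(graphs), function(i) {
    metric_vector(graphs[[i]], n_null = n_null, n_rewire = n_rewire,
                  seed = mix_seed(seed, i),
                  modularity_restarts = modularity_restarts)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(participant_id = ids, stringsAsFactors = FALSE), out)
}
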