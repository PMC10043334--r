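# Brute-force oracle twins for the graph-metric battery, plus small fixture
# builders. Oracles are deliberately written as direct enumerations,
# independent of the package's vectorized implementations.

rand_directed_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(as.numeric(runif(n * n) < p), n, n)
  diag(A) <- 0
  A
}

rand_undirected_graph <- function(n, p, seed) {
  A <- rand_directed_graph(n, p, seed)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

rand_weighted_graph <- function(n, p, seed) {
  A <- rand_directed_graph(n, p, seed)
  set.seed(seed + 1)
  A * matrix(rnorm(n * n), n, n)
}

oracle_degree <- function(A, directed) {
  cnt <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (i != j && A[i, j] != 0) cnt <- cnt + 1
  }
  if (directed) cnt else cnt / 2
}

oracle_strength <- function(W, directed) {
  n <- nrow(W)
  s <- numeric(n)
  for (i in seq_len(n)) {
    out_s <- 0; in_s <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      out_s <- out_s + abs(W[i, j]); in_s <- in_s + abs(W[j, i])
    }
    s[i] <- if (directed) (out_s + in_s) / 2 else out_s
  }
  mean(s)
}

# directed clustering/transitivity by explicit triangle-orientation counting
oracle_clust_trans_dir <- function(A) {
  n <- nrow(A)
  num <- den <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      t_i <- t_i + (A[i, j] + A[j, i]) * (A[i, k] + A[k, i]) *
        (A[j, k] + A[k, j])
    }
    t_i <- t_i / 2
    d_tot <- sum(A[i, -i]) + sum(A[-i, i])
    d_bi <- sum(A[i, -i] * A[-i, i])
    num[i] <- t_i
    den[i] <- d_tot * (d_tot - 1) - 2 * d_bi
  }
  c(clustering = mean(ifelse(den > 0, num / den, 0)),
    transitivity = if (sum(den) > 0) sum(num) / sum(den) else 0)
}

oracle_clust_trans_undir <- function(A) {
  n <- nrow(A)
  tri <- k <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) for (m in seq_len(n)) {
      if (j >= m || j == i || m == i) next
      if (A[i, j] && A[i, m] && A[j, m]) t_i <- t_i + 1
    }
    tri[i] <- t_i
    k[i] <- sum(A[i, -i])
  }
  den <- k * (k - 1) / 2
  c(clustering = mean(ifelse(den > 0, tri / den, 0)),
    transitivity = if (sum(den) > 0) sum(tri) / sum(den) else 0)
}

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_eff_cpl <- function(A) {
  D <- oracle_floyd_warshall(A)
  off <- D[row(D) != col(D)]
  c(global_efficiency = mean(ifelse(is.finite(off), 1 / off, 0)),
    characteristic_path_length =
      if (any(is.finite(off))) mean(off[is.finite(off)]) else NA_real_)
}

oracle_assort <- function(A, directed) {
  xs <- ys <- numeric(0)
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || A[i, j] == 0) next
    if (directed) {
      xs <- c(xs, sum(A[, i]))   # in-degree of source
      ys <- c(ys, sum(A[j, ]))   # out-degree of target
    } else {
      xs <- c(xs, sum(A[i, ]))
      ys <- c(ys, sum(A[j, ]))
    }
  }
  if (length(xs) < 2 || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  cor(xs, ys)
}

oracle_flow <- function(A) {
  n <- nrow(A)
  fc <- numeric(n)
  for (v in seq_len(n)) {
    nbrs <- setdiff(which(A[v, ] > 0 | A[, v] > 0), v)
    if (length(nbrs) < 2) next
    pairs <- expand.grid(i = nbrs, j = nbrs)
    pairs <- pairs[pairs$i != pairs$j, ]
    open <- mapply(function(i, j) A[i, j] == 0, pairs$i, pairs$j)
    if (!any(open)) next
    thru <- mapply(function(i, j) A[i, v] > 0 && A[v, j] > 0,
                   pairs$i[open], pairs$j[open])
    fc[v] <- mean(thru)
  }
  mean(fc)
}

# all set partitions of n elements as restricted growth strings (columns)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (c in seq_len(maxc + 1L)) rec(c(prefix, c), max(maxc, c))
  }
  rec(1L, 1L)
  do.call(cbind, out)
}

oracle_modularity_exhaustive <- function(A) {
  n <- nrow(A)
  m <- sum(A)
  B <- A / m - outer(rowSums(A), colSums(A)) / m^2
  parts <- all_partitions(n)
  Qs <- rep(sum(diag(B)), ncol(parts))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Qs <- Qs + B[i, j] * (parts[i, ] == parts[j, ])
  }
  max(Qs)
}

# residual-regression partial correlation (the independent route)
oracle_partial_cor <- function(X, i, j) {
  o <- setdiff(seq_len(ncol(X)), c(i, j))
  Z <- cbind(1, X[, o, drop = FALSE])
  ri <- .lm.fit(Z, X[, i])$residuals
  rj <- .lm.fit(Z, X[, j])$residuals
  cor(ri, rj)
}

# Watts-Strogatz ring lattice with rewiring probability p
ws_ring <- function(n, k, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  e <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  for (idx in seq_len(nrow(e))) {
    if (runif(1) < p) {
      i <- e[idx, 1]; j <- e[idx, 2]
      cand <- setdiff(which(A[i, ] == 0), i)
      if (length(cand)) {
        jn <- cand[sample.int(length(cand), 1)]
        A[i, j] <- A[j, i] <- 0
        A[i, jn] <- A[jn, i] <- 1
      }
    }
  }
  A
}

chain_system <- function(strength = 0.8) {
  causal_system(3, data.frame(source = c(1, 2), target = c(2, 3),
                              kind = "sigmoid", strength = strength, lag = 1))
}

fast_dsn <- function(seed = 1L, k = 5L) dsn_config(seed = seed, k = k)
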