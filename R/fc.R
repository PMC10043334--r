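#' Conditional partial Pearson correlation matrix
#'
#' Partial correlation of every region pair given all other regions,
#' computed from the precision matrix: `r_ij = -P_ij / sqrt(P_ii P_jj)`
#' with `P = solve(cov(series))`. This equals the Pearson correlation of
#' the residuals of i and j after regressing each on the remaining R - 2
#' columns.
#'
#' @param series T x R numeric matrix (T > R + 2, non-constant columns).
#' @return Symmetric R x R matrix with zero diagonal.
#' @export
partial_correlation_matrix <- function(series) {
  stopifnot(is.matrix(series))
  T_ <- nrow(series); R <- ncol(series)
  if (T_ <= R + 2) stop("need T > R + 2 samples to condition on R - 2 regions")
  if (any(apply(series, 2, stats::sd) == 0)) {
    stop("degenerate input: constant column")
  }
  S <- stats::cov(series)
  P <- tryCatch(solve(S), error = function(e) {
    stop("singular covariance (collinear regions): ", conditionMessage(e))
  })
  D <- 1 / sqrt(diag(P))
  pc <- -P * outer(D, D)
  diag(pc) <- 0
  pc <- (pc + t(pc)) / 2  # enforce exact symmetry against round-off
  dimnames(pc) <- dimnames(S)
  pc
}

#' Two-tailed significance of a (partial) correlation
#'
#' Student-t test of a correlation computed with `n_conditioned` variables
#' partialled out: `t = r * sqrt(df / (1 - r^2))` with
#' `df = T - 2 - n_conditioned`.
#'
#' @param r Correlation value(s), |r| < 1 (vectorized).
#' @param T Number of samples.
#' @param n_conditioned Number of conditioned variables (R - 2 for a full
#'   conditional correlation matrix).
#' @return Two-tailed p value(s) in \[0, 1\].
#' @export
fc_significance <- function(r, T, n_conditioned = 0) {
  df <- T - 2 - n_conditioned
  if (df <= 0) stop("degrees of freedom must be positive")
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df = df)
}

#' Individual-level functional connectivity graph
#'
#' Computes the conditional partial correlation matrix of one scan and
#' retains entries whose two-tailed p value falls below `alpha`; retained
#' weights keep their sign.
#'
#' @param series T x R matrix for one participant.
#' @param alpha Significance level in (0, 1].
#' @return An `fc_graph` (also `connectivity_graph`) with symmetric weights
#'   and mask, plus an `edges` data.frame (roi_a, roi_b, partial_r, p).
#' @export
individual_fc_graph <- function(series, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  pc <- partial_correlation_matrix(series)
  R <- ncol(pc)
  labels <- colnames(pc) %||% paste0("ROI", seq_len(R))
  p <- matrix(1, R, R)
  off <- upper.tri(pc)
  p[off] <- fc_significance(pc[off], T = nrow(series), n_conditioned = R - 2)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  mask <- if (alpha >= 1) off | t(off) else p < alpha & (off | t(off))
  weights <- ifelse(mask, pc, 0)
  ij <- which(off, arr.ind = TRUE)
  edges <- data.frame(roi_a = labels[ij[, 1]], roi_b = labels[ij[, 2]],
                      partial_r = pc[off], p = p[off],
                      stringsAsFactors = FALSE)
  g <- make_graph(labels, weights, mask, directed = FALSE, edges = edges,
                  alpha = alpha, subclass = "fc_graph")
  g
}

#' Group consensus functional connectivity graph
#'
#' Element-wise mean of the individual weight matrices. Weights are kept as
#' the raw mean (no re-thresholding); the mask marks positive consensus
#' weights and is intended for display.
#'
#' @param graphs Non-empty list of `fc_graph` objects sharing region labels.
#' @return An `fc_graph` holding the consensus weights.
#' @export
group_consensus_fc <- function(graphs) {
  if (!length(graphs)) stop("empty graph list")
  labels <- graphs[[1]]$roi_labels
  for (g in graphs) {
    if (!identical(g$roi_labels, labels)) {
      stop("all graphs must share the same region labels")
    }
  }
  W <- Reduce(`+`, lapply(graphs, `[[`, "weights")) / length(graphs)
  make_graph(labels, W, mask = W > 0, directed = FALSE,
             alpha = NA_real_, subclass = "fc_graph")
}
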