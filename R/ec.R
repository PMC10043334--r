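#' Training configuration for the stacked convolution predictor
#'
#' Hyperparameters of the deep stacking network used to reconstruct a
#' target region's signal from lagged input signals: each input series gets
#' a small adaptive-kernel convolution module (six 1x2 filters with bias,
#' PReLU slopes per filter) and module outputs are combined by a learned
#' element-wise weighted sum. Optimized with minibatch Adam
#' (beta1 = 0.9, beta2 = 0.999) at learning rate 0.001 on mean squared
#' error, with early stopping on a held-out validation fraction.
#'
#' @param k Cross-validation fold count for edge estimation (>= 2).
#' @param n_filters Number of convolution filters per module; also the
#'   adaptive-kernel length in samples.
#' @param filter_width Filter width in samples; predictors only ever see
#'   strictly past samples.
#' @param learning_rate,beta1,beta2 Adam parameters.
#' @param n_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (0 disables early stopping and the validation split).
#' @param val_frac Fraction of training samples held out for early stopping.
#' @param gc_type `"log_ratio"` for `ln(MSE_reduced / MSE_full)` (default)
#'   or `"difference"` for `MSE_reduced - MSE_full`.
#' @param seed Integer master seed; all per-edge, per-fold seeds are derived
#'   from it deterministically.
#' @return An object of class `dsn_config`.
#' @export
dsn_config <- function(k = 5L, n_filters = 6L, filter_width = 2L,
                       learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                       n_epochs = 60L, batch_size = 64L,
                       early_stop_patience = 8L, val_frac = 0.2,
                       gc_type = c("log_ratio", "difference"), seed = 1L) {
  gc_type <- match.arg(gc_type)
  if (k < 2) stop("k must be at least 2")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(k = as.integer(k), n_filters = as.integer(n_filters),
                 filter_width = as.integer(filter_width),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_frac = val_frac, gc_type = gc_type,
                 seed = as.integer(seed)),
            class = "dsn_config")
}

# normalise series input to a list of T x R matrices
as_series_list <- function(x) {
  if (is.matrix(x)) list(x)
  else if (inherits(x, "cohort_ts")) x$series
  else if (is.list(x)) x
  else stop("series must be a matrix, a list of matrices, or a cohort_ts")
}

# lag matrices (one per input index) + aligned target vector, pooled over
# participants; column j of a lag matrix holds lag j
build_lagged <- function(series_list, input_idx, target_idx, L) {
  Xs <- vector("list", length(input_idx))
  ys <- list()
  for (m in seq_along(input_idx)) Xs[[m]] <- list()
  for (s in seq_along(series_list)) {
    S <- series_list[[s]]
    T_ <- nrow(S)
    if (T_ <= L + 1L) stop("series too short for the requested lags")
    rows <- (L + 1L):T_
    for (m in seq_along(input_idx)) {
      i <- input_idx[m]
      Xs[[m]][[s]] <- vapply(seq_len(L), function(j) S[rows - j, i],
                             numeric(length(rows)))
    }
    ys[[s]] <- S[rows, target_idx]
  }
  list(X = lapply(Xs, function(l) do.call(rbind, l)),
       y = unlist(ys, use.names = FALSE))
}

dsn_seed <- function(config, target_idx, input_idx, tag = 0L) {
  mix_seed(config$seed, target_idx, hash_index_set(input_idx), tag)
}

# train on train_series, return held-out MSE on eval_series (internal core)
dsn_eval_mse <- function(input_idx, target_idx, train_series, eval_series,
                         config, seed) {
  L <- max(config$n_filters, config$filter_width)
  tr <- build_lagged(train_series, input_idx, target_idx, L)
  ev <- build_lagged(eval_series, input_idx, target_idx, L)
  if (stats::sd(tr$y) == 0) stop("degenerate input: constant target series")
  fit <- cpp_dsn_fit(tr$X, tr$y, ev$X, ev$y,
                     config$n_filters, config$filter_width,
                     config$learning_rate, config$beta1, config$beta2,
                     config$n_epochs, config$early_stop_patience,
                     config$batch_size, config$val_frac, seed)
  fit$eval_mse
}

#' Held-out reconstruction error of one region from a set of input regions
#'
#' Trains the stacked convolution predictor to reconstruct the target
#' region's signal at time t from strictly past samples of the input
#' regions (the target's own past is always included), then returns the
#' mean squared prediction error on the evaluation series. Deterministic
#' given (data, config): the training seed is derived from the config seed,
#' the target and the input set.
#'
#' @param target_index Target region (1-based column index).
#' @param input_set Integer vector of input region indices; the target is
#'   added if absent.
#' @param train_series,eval_series A T x R matrix, list of such matrices, or
#'   [simulate_cohort()] output.
#' @param config A [dsn_config()].
#' @param seed_tag Optional extra integer mixed into the derived seed (used
#'   internally to separate cross-validation folds).
#' @return Non-negative held-out mean squared error.
#' @export
reconstruction_error <- function(target_index, input_set, train_series,
                                 eval_series, config = dsn_config(),
                                 seed_tag = 0L) {
  train_series <- as_series_list(train_series)
  eval_series <- as_series_list(eval_series)
  input_set <- sort(unique(c(as.integer(input_set), as.integer(target_index))))
  dsn_eval_mse(input_set, target_index, train_series, eval_series, config,
               dsn_seed(config, target_index, input_set, seed_tag))
}

#' Conditional Granger causality index for one directed pair
#'
#' Measures the improvement in reconstructing the target when the source is
#' added to a model that already contains the target's own past and all
#' conditioning regions: `ln(MSE_reduced / MSE_full)` evaluated on held-out
#' data (or the raw difference, per config). Positive values mean the
#' source carries predictive information about the target beyond what the
#' conditioning set explains.
#'
#' @param source,target Region indices; `source` must not be in
#'   `conditioning`, nor equal `target`.
#' @param conditioning Indices of the regions conditioned on (typically all
#'   remaining regions).
#' @inheritParams reconstruction_error
#' @return The Granger causality index (real; unbounded).
#' @export
gc_index <- function(source, target, conditioning, train_series, eval_series,
                     config = dsn_config(), seed_tag = 0L) {
  if (source %in% conditioning || target %in% conditioning) {
    stop("source and target must not appear in the conditioning set")
  }
  if (source == target) stop("source must differ from target")
  train_series <- as_series_list(train_series)
  eval_series <- as_series_list(eval_series)
  reduced <- sort(unique(c(as.integer(target), as.integer(conditioning))))
  full <- sort(unique(c(reduced, as.integer(source))))
  mse_red <- dsn_eval_mse(reduced, target, train_series, eval_series, config,
                          dsn_seed(config, target, reduced, seed_tag))
  mse_full <- dsn_eval_mse(full, target, train_series, eval_series, config,
                           dsn_seed(config, target, full, seed_tag))
  if (mse_full <= 0) stop("perfect fit (MSE = 0): degenerate or overfit data")
  if (config$gc_type == "log_ratio") log(mse_red / mse_full)
  else mse_red - mse_full
}

# one-tailed t-test of mean > 0 over K fold estimates
gc_t_test <- function(samples) {
  k <- length(samples)
  m <- mean(samples)
  s <- stats::sd(samples)
  if (s == 0) {
    t <- if (m > 0) Inf else if (m < 0) -Inf else 0
  } else {
    t <- m / (s / sqrt(k))
  }
  list(mean = m, t = t, p = stats::pt(t, df = k - 1, lower.tail = FALSE))
}

# shared inner loop: per (target, fold) train the full model once and one
# reduced model per source, so each edge costs one extra training run
gc_fold_matrix <- function(train_series, eval_series, config, fold_tag) {
  R <- ncol(train_series[[1]])
  gc <- matrix(NA_real_, R, R)
  for (target in seq_len(R)) {
    full <- seq_len(R)
    mse_full <- dsn_eval_mse(full, target, train_series, eval_series, config,
                             dsn_seed(config, target, full, fold_tag))
    if (mse_full <= 0) stop("perfect fit (MSE = 0) for region ", target)
    for (source in setdiff(seq_len(R), target)) {
      reduced <- setdiff(full, source)
      mse_red <- dsn_eval_mse(reduced, target, train_series, eval_series,
                              config,
                              dsn_seed(config, target, reduced, fold_tag))
      gc[source, target] <- if (config$gc_type == "log_ratio") {
        log(mse_red / mse_full)
      } else {
        mse_red - mse_full
      }
    }
  }
  gc
}

make_graph <- function(roi_labels, weights, mask, directed, edges = NULL,
                       alpha = NA_real_, subclass) {
  dimnames(weights) <- list(roi_labels, roi_labels)
  dimnames(mask) <- list(roi_labels, roi_labels)
  structure(list(roi_labels = roi_labels, weights = weights, mask = mask,
                 directed = directed, edges = edges, alpha = alpha),
            class = c(subclass, "connectivity_graph"))
}

#' Group-level effective connectivity graph
#'
#' Partitions the cohort's scans into K folds; for each fold the predictor
#' is trained on the other K-1 folds and the conditional Granger causality
#' index of every ordered region pair is evaluated on the held-out fold.
#' An edge source -> target is drawn when a one-tailed t-test across the K
#' fold indices rejects mean <= 0 at `alpha`; its weight is the mean index.
#' Conditioning is on all remaining regions.
#'
#' @param cohort A [simulate_cohort()] object, or list of T x R matrices.
#' @param config A [dsn_config()]; `config$k` folds are used.
#' @param alpha Edge-wise significance level in (0, 1].
#' @param fdr Apply Benjamini-Hochberg correction across edges before
#'   thresholding (default `FALSE`: each edge tested at `alpha`).
#' @param progress Print per-fold progress messages.
#' @return An `ec_graph` (also `connectivity_graph`): region labels, R x R
#'   weight matrix, significance mask, and an `edges` data.frame with the
#'   per-fold indices, mean, t statistic and one-tailed p for every ordered
#'   pair.
#' @export
group_ec_graph <- function(cohort, config = dsn_config(), alpha = 0.05,
                           fdr = FALSE, progress = FALSE) {
  series <- as_series_list(cohort)
  n <- length(series)
  K <- config$k
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (K > n) stop("K exceeds the number of participants")
  R <- ncol(series[[1]])
  labels <- colnames(series[[1]]) %||% paste0("ROI", seq_len(R))

  fold_of <- with_seed(mix_seed(config$seed, 5501L),
                       sample(rep_len(seq_len(K), n)))
  gc_folds <- array(NA_real_, c(R, R, K))
  for (k in seq_len(K)) {
    if (progress) message(sprintf("EC fold %d/%d", k, K))
    train <- series[fold_of != k]
    eval_ <- series[fold_of == k]
    gc_folds[, , k] <- gc_fold_matrix(train, eval_, config, fold_tag = k)
  }

  finish_ec_graph(gc_folds, labels, alpha, fdr)
}

finish_ec_graph <- function(gc_folds, labels, alpha, fdr) {
  R <- dim(gc_folds)[1]
  K <- dim(gc_folds)[3]
  idx <- which(row(diag(R)) != col(diag(R)), arr.ind = TRUE)
  est <- data.frame(source = labels[idx[, 1]], target = labels[idx[, 2]],
                    stringsAsFactors = FALSE)
  folds_mat <- t(vapply(seq_len(nrow(idx)),
                        function(e) gc_folds[idx[e, 1], idx[e, 2], ],
                        numeric(K)))
  colnames(folds_mat) <- paste0("gc_fold", seq_len(K))
  stats_list <- lapply(seq_len(nrow(idx)), function(e) gc_t_test(folds_mat[e, ]))
  est$mean_gc <- vapply(stats_list, `[[`, numeric(1), "mean")
  est$t_stat <- vapply(stats_list, `[[`, numeric(1), "t")
  est$p_one_tailed <- vapply(stats_list, `[[`, numeric(1), "p")
  p_use <- if (fdr) stats::p.adjust(est$p_one_tailed, "BH") else est$p_one_tailed
  sig <- if (alpha >= 1) rep(TRUE, nrow(est)) else p_use < alpha

  weights <- matrix(0, R, R)
  mask <- matrix(FALSE, R, R)
  mask[idx[sig, , drop = FALSE]] <- TRUE
  weights[idx[sig, , drop = FALSE]] <- est$mean_gc[sig]
  est <- cbind(est[, c("source", "target")], as.data.frame(folds_mat),
               est[, c("mean_gc", "t_stat", "p_one_tailed")])
  make_graph(labels, weights, mask, directed = TRUE, edges = est,
             alpha = alpha, subclass = "ec_graph")
}

#' Individual-level effective connectivity graph
#'
#' Removes one participant's scan, randomly partitions the remaining scans
#' into K disjoint sets, trains the predictor on each set, and evaluates
#' every pair's conditional Granger causality index on the omitted scan
#' only. Edges are drawn by the same one-tailed t-test across the K
#' estimates.
#'
#' @inheritParams group_ec_graph
#' @param participant_id Id (or index) of the participant whose graph is
#'   estimated.
#' @return An `ec_graph` for that participant.
#' @export
individual_ec_graph <- function(cohort, participant_id,
                                config = dsn_config(), alpha = 0.05,
                                fdr = FALSE) {
  series <- as_series_list(cohort)
  n <- length(series)
  if (n < 2) stop("individual-level graphs need a cohort of at least 2")
  if (is.character(participant_id)) {
    pidx <- match(participant_id, names(series))
    if (is.na(pidx)) stop("unknown participant: ", participant_id)
  } else pidx <- as.integer(participant_id)
  K <- config$k
  if (K > n - 1) stop("K exceeds the number of remaining participants")
  R <- ncol(series[[1]])
  labels <- colnames(series[[1]]) %||% paste0("ROI", seq_len(R))

  rest <- series[-pidx]
  part <- with_seed(mix_seed(config$seed, 7707L, pidx),
                    sample(rep_len(seq_len(K), n - 1)))
  eval_ <- series[pidx]
  gc_folds <- array(NA_real_, c(R, R, K))
  for (k in seq_len(K)) {
    gc_folds[, , k] <- gc_fold_matrix(rest[part == k], eval_, config,
                                      fold_tag = mix_seed(0L, pidx, k))
  }
  finish_ec_graph(gc_folds, labels, alpha, fdr)
}

#' Re-threshold an effective connectivity graph at a new alpha
#'
#' Rebuilds the significance mask and weights from the stored per-edge
#' t-test p values without retraining any model.
#'
#' @param graph An `ec_graph` from [group_ec_graph()] or
#'   [individual_ec_graph()].
#' @param alpha New edge-wise significance level in (0, 1].
#' @param fdr Apply Benjamini-Hochberg correction before thresholding.
#' @return An `ec_graph` with updated mask and weights.
#' @export
rethreshold_graph <- function(graph, alpha, fdr = FALSE) {
  stopifnot(inherits(graph, "ec_graph"), !is.null(graph$edges))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  est <- graph$edges
  p_use <- if (fdr) stats::p.adjust(est$p_one_tailed, "BH") else est$p_one_tailed
  sig <- if (alpha >= 1) rep(TRUE, nrow(est)) else p_use < alpha
  R <- length(graph$roi_labels)
  weights <- matrix(0, R, R)
  mask <- matrix(FALSE, R, R)
  src <- match(est$source, graph$roi_labels)
  tgt <- match(est$target, graph$roi_labels)
  mask[cbind(src[sig], tgt[sig])] <- TRUE
  weights[cbind(src[sig], tgt[sig])] <- est$mean_gc[sig]
  make_graph(graph$roi_labels, weights, mask, directed = TRUE, edges = est,
             alpha = alpha, subclass = "ec_graph")
}

#' Analytic linear conditional Granger causality (OLS oracle)
#'
#' The classic parametric counterpart of [gc_index()]: fits two linear
#' autoregressions by ordinary least squares — the reduced model on lagged
#' target + conditioning signals, the full model adding the lagged source —
#' and returns `ln(RSS_reduced / RSS_full)`. Used as an independent
#' cross-check of the nonlinear estimator on linear systems.
#'
#' @inheritParams gc_index
#' @param series A T x R matrix, list of matrices, or cohort; pooled.
#' @param lags Number of past samples per input (default 2).
#' @return Linear Granger log-variance ratio (>= 0 in-sample).
#' @export
linear_gc_index <- function(source, target, conditioning, series, lags = 2L) {
  series <- as_series_list(series)
  reduced <- sort(unique(c(target, conditioning)))
  full <- sort(unique(c(reduced, source)))
  rss <- function(input_idx) {
    d <- build_lagged(series, input_idx, target, lags)
    X <- cbind(1, do.call(cbind, d$X))
    fit <- stats::lm.fit(X, d$y)
    sum(fit$residuals^2)
  }
  log(rss(reduced) / rss(full))
}

#' @export
print.connectivity_graph <- function(x, ...) {
  kind <- if (x$directed) "directed (effective connectivity)"
          else "undirected (functional connectivity)"
  n_edges <- if (x$directed) sum(x$mask) else sum(x$mask) / 2
  cat(sprintf("Connectivity graph: %d regions, %s\n",
              length(x$roi_labels), kind))
  cat(sprintf("  %d significant edge(s)%s\n", n_edges,
              if (!is.na(x$alpha)) sprintf(" at alpha = %g", x$alpha) else ""))
  invisible(x)
}

#' @export
summary.connectivity_graph <- function(object, ...) {
  print(object)
  w <- object$weights[object$mask]
  if (length(w)) {
    cat(sprintf("  edge weights: min %.3g, median %.3g, max %.3g\n",
                min(w), stats::median(w), max(w)))
  }
  if (!is.null(object$edges)) {
    cat("  top edges by |weight|:\n")
    e <- object$edges
    ord <- order(-abs(e$mean_gc %||% e$partial_r))
    print(utils::head(e[ord, ], 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.connectivity_graph <- function(x, main = NULL, ...) {
  R <- length(x$roi_labels)
  w <- x$weights
  graphics::image(seq_len(R), seq_len(R), t(w[R:1, , drop = FALSE]),
                  axes = FALSE, xlab = "target", ylab = "source",
                  main = main %||% "connectivity weights", ...)
  graphics::axis(1, at = seq_len(R), labels = x$roi_labels, las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(R), labels = rev(x$roi_labels), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
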