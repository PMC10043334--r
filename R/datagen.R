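#' Define a synthetic causal system over a set of regions
#'
#' A `causal_system` describes the ground truth used to generate synthetic
#' regional time series: a set of directed couplings between regions, each
#' with a functional form, strength and lag, on top of first-order
#' autoregressive self-dynamics and Gaussian innovation noise. It stands in
#' for the (unobservable) causal structure among brain regions and gives
#' validation code a known answer to recover.
#'
#' @param n_rois Number of regions (nodes).
#' @param edges `data.frame` with columns `source`, `target` (1-based region
#'   indices), `kind` (one of `"linear"`, `"quadratic"`, `"sigmoid"`,
#'   `"threshold"`), `strength` (real coupling coefficient) and `lag`
#'   (integer number of samples, at least 1). `NULL` means no couplings.
#' @param noise_sd Innovation standard deviation, must be positive.
#' @param self_decay AR(1) self-coupling in (0, 1).
#' @param roi_labels Optional character labels, defaults to `ROI1..ROIn`.
#' @param check_stationary If `TRUE` (default) a probe series is simulated
#'   and the system is rejected when its variance drifts (variance of the
#'   last quarter more than 3x away from the second quarter's).
#'
#' @details Coupling forms applied to `u = strength * x_source(t - lag)`:
#'   linear `u`; quadratic `u^2 - 1` (mean-removed for standardized inputs);
#'   sigmoid `tanh(u)`; threshold `u * 1(|u| > 0.5)` (dead-zone).
#'
#' @return An object of class `causal_system`.
#' @seealso [simulate_system()], [simulate_cohort()]
#' @export
causal_system <- function(n_rois, edges = NULL, noise_sd = 1,
                          self_decay = 0.3, roi_labels = NULL,
                          check_stationary = TRUE) {
  stopifnot_scalar(n_rois, "n_rois")
  stopifnot_scalar(noise_sd, "noise_sd")
  stopifnot_scalar(self_decay, "self_decay")
  if (n_rois < 1) stop("n_rois must be at least 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (self_decay <= 0 || self_decay >= 1) stop("self_decay must lie in (0, 1)")
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(n_rois))
  stopifnot(length(roi_labels) == n_rois)

  if (is.null(edges)) {
    edges <- data.frame(source = integer(), target = integer(),
                        kind = character(), strength = numeric(),
                        lag = integer())
  }
  edges <- as.data.frame(edges)
  needed <- c("source", "target", "kind", "strength", "lag")
  if (!all(needed %in% names(edges))) {
    stop("edges must have columns source, target, kind, strength, lag")
  }
  edges$source <- as.integer(edges$source)
  edges$target <- as.integer(edges$target)
  edges$lag <- as.integer(edges$lag)
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    if (any(edges$lag < 1L)) stop("all lags must be >= 1 (strictly past-to-future)")
    if (any(edges$source < 1L | edges$source > n_rois |
            edges$target < 1L | edges$target > n_rois)) {
      stop("edge endpoints out of range")
    }
    if (!all(edges$kind %in% c("linear", "quadratic", "sigmoid", "threshold"))) {
      stop("unknown coupling kind")
    }
  }

  sys <- structure(
    list(n_rois = as.integer(n_rois), edges = edges,
         noise_sd = noise_sd, self_decay = self_decay,
         roi_labels = roi_labels),
    class = "causal_system")

  if (check_stationary) {
    probe <- simulate_system(sys, n_timepoints = 400, seed = 760013L,
                             z_score = FALSE)
    q2 <- apply(probe[101:200, , drop = FALSE], 2, stats::var)
    q4 <- apply(probe[301:400, , drop = FALSE], 2, stats::var)
    if (any(q4 > 3 * q2 + 1e-12) || any(q2 > 3 * q4 + 1e-12)) {
      stop("system failed the bounded-variance stationarity check; ",
           "reduce coupling strengths or self_decay")
    }
  }
  sys
}

#' @export
print.causal_system <- function(x, ...) {
  cat(sprintf("Causal system: %d regions, %d directed coupling(s)\n",
              x$n_rois, nrow(x$edges)))
  cat(sprintf("  self_decay = %.3g, noise_sd = %.3g\n",
              x$self_decay, x$noise_sd))
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      e <- x$edges[i, ]
      cat(sprintf("  %s -> %s  %s  strength %.3g  lag %d\n",
                  x$roi_labels[e$source], x$roi_labels[e$target],
                  e$kind, e$strength, e$lag))
    }
  }
  invisible(x)
}

coupling_fun <- function(kind) {
  switch(kind,
         linear    = function(u) u,
         quadratic = function(u) u^2 - 1,
         sigmoid   = function(u) tanh(u),
         threshold = function(u) u * (abs(u) > 0.5),
         stop("unknown coupling kind: ", kind))
}

#' Simulate one multivariate time series from a causal system
#'
#' Generates `x_j(t) = self_decay * x_j(t-1) + sum over incoming edges of
#' f_kind(strength * x_i(t - lag)) + eps`, with Gaussian innovations, a
#' 100-sample burn-in that is discarded, and per-column z-scoring, so the
#' output resembles preprocessed, standardized regional signals.
#'
#' @param system A [causal_system()].
#' @param n_timepoints Number of retained samples (>= 50).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param strengths Optional vector overriding the per-edge strengths (used
#'   for between-participant variation).
#' @param z_score Standardize each column (default `TRUE`).
#' @param burn_in Samples discarded at the start (default 100).
#' @return A `n_timepoints x n_rois` numeric matrix, columns named by region.
#' @export
simulate_system <- function(system, n_timepoints, seed, strengths = NULL,
                            z_score = TRUE, burn_in = 100L) {
  stopifnot(inherits(system, "causal_system"))
  stopifnot_scalar(n_timepoints, "n_timepoints")
  if (n_timepoints < 50) stop("n_timepoints must be at least 50")
  edges <- system$edges
  if (!is.null(strengths)) {
    stopifnot(length(strengths) == nrow(edges))
    edges$strength <- strengths
  }
  R <- system$n_rois
  maxlag <- max(1L, if (nrow(edges)) max(edges$lag) else 1L)
  total <- n_timepoints + burn_in + maxlag
  funs <- lapply(edges$kind, coupling_fun)

  x <- with_seed(seed, {
    eps <- matrix(stats::rnorm(total * R, sd = system$noise_sd), total, R)
    x <- matrix(0, total, R)
    x[seq_len(maxlag), ] <- eps[seq_len(maxlag), ]
    d <- system$self_decay
    for (t in (maxlag + 1L):total) {
      xt <- d * x[t - 1L, ] + eps[t, ]
      if (nrow(edges)) {
        for (e in seq_len(nrow(edges))) {
          u <- edges$strength[e] * x[t - edges$lag[e], edges$source[e]]
          xt[edges$target[e]] <- xt[edges$target[e]] + funs[[e]](u)
        }
      }
      if (any(abs(xt) > 1e6)) {
        stop("series diverged (|value| > 1e6): non-stationary parameterization")
      }
      x[t, ] <- xt
    }
    x
  })

  out <- x[(burn_in + maxlag + 1L):total, , drop = FALSE]
  colnames(out) <- system$roi_labels
  if (z_score) {
    sds <- apply(out, 2, stats::sd)
    if (any(sds == 0)) stop("degenerate series: zero-variance column")
    out <- scale(out)
    attributes(out)[c("scaled:center", "scaled:scale")] <- NULL
  }
  out
}

#' Simulate a cohort of participants from one causal system
#'
#' Every participant shares the system's topology; coupling strengths are
#' jittered per participant by `Normal(0, between_subject_sd^2)`, truncated
#' so that each edge keeps its sign. Per-participant seeds are derived
#' deterministically from the master seed.
#'
#' @param system A [causal_system()].
#' @param n_participants Cohort size (>= 2).
#' @param n_timepoints Samples per participant.
#' @param between_subject_sd Standard deviation of the strength jitter
#'   (>= 0; 0 means identical strengths).
#' @param seed Master integer seed.
#' @param sampling_interval Sampling interval in seconds (default 3, the
#'   usual BOLD repetition time at this resolution).
#' @return An object of class `cohort_ts`: list with `participant_ids`,
#'   `series` (named list of T x R matrices), `sampling_interval`, `system`
#'   and the per-participant `strengths` matrix.
#' @export
simulate_cohort <- function(system, n_participants, n_timepoints,
                            between_subject_sd = 0, seed = 1L,
                            sampling_interval = 3) {
  stopifnot(inherits(system, "causal_system"))
  stopifnot_scalar(n_participants, "n_participants")
  if (n_participants < 2) stop("n_participants must be at least 2")
  if (between_subject_sd < 0) stop("between_subject_sd must be >= 0")

  ids <- sprintf("P%03d", seq_len(n_participants))
  n_edges <- nrow(system$edges)
  base <- system$edges$strength
  strengths <- matrix(rep(base, each = n_participants),
                      nrow = n_participants, ncol = n_edges)
  if (n_edges > 0 && between_subject_sd > 0) {
    jit <- with_seed(mix_seed(seed, 9001L), {
      matrix(stats::rnorm(n_participants * n_edges, sd = between_subject_sd),
             n_participants, n_edges)
    })
    prop <- strengths + jit
    # truncate at (almost) zero so the edge sign never flips
    flip <- sign(prop) != sign(strengths)
    prop[flip] <- sign(strengths[flip]) * 1e-3
    strengths <- prop
  }

  series <- vector("list", n_participants)
  names(series) <- ids
  for (p in seq_len(n_participants)) {
    series[[p]] <- simulate_system(
      system, n_timepoints, seed = mix_seed(seed, p),
      strengths = if (n_edges) strengths[p, ] else NULL)
  }

  structure(
    list(participant_ids = ids, series = series,
         sampling_interval = sampling_interval, system = system,
         strengths = strengths, seed = as.integer(seed)),
    class = "cohort_ts")
}

#' @export
print.cohort_ts <- function(x, ...) {
  d <- dim(x$series[[1]])
  cat(sprintf(
    "Synthetic cohort: %d participants, %d timepoints x %d regions (TR %gs)\n",
    length(x$series), d[1], d[2], x$sampling_interval))
  cat(sprintf("  ground truth: %d planted directed coupling(s)\n",
              nrow(x$system$edges)))
  invisible(x)
}

#' Ground-truth adjacency of the system behind a cohort or system object
#'
#' @param x A `causal_system` or `cohort_ts`.
#' @return Logical R x R matrix, entry `[i, j]` `TRUE` when a planted
#'   coupling i -> j exists.
#' @export
true_adjacency <- function(x) {
  sys <- if (inherits(x, "cohort_ts")) x$system else x
  stopifnot(inherits(sys, "causal_system"))
  A <- matrix(FALSE, sys$n_rois, sys$n_rois,
              dimnames = list(sys$roi_labels, sys$roi_labels))
  if (nrow(sys$edges)) {
    A[cbind(sys$edges$source, sys$edges$target)] <- TRUE
  }
  A
}

#' Generate a participant covariate table with planted metric associations
#'
#' Builds a synthetic table of demographic, cardiometabolic and cognitive
#' covariates for the participants of a cohort. Covariates named in
#' `planted` are constructed as `beta * z(metric) + loadings on nuisance
#' demographics + Normal(0, noise_sd^2)`, so the generating `beta` is the
#' true coefficient of the z-scored metric in a covariate-on-metric
#' regression that adjusts for the same demographics; all other covariates
#' are independent noise on realistic scales. Binary covariates are formed
#' by thresholding a latent Gaussian at its median (50/50 split).
#'
#' @param metrics `data.frame` with a `participant_id` column and one column
#'   per graph metric (one row per participant).
#' @param planted List of `list(covariate=, metric=, beta=)` entries; may be
#'   empty for a global-null table.
#' @param noise_sd Residual standard deviation of planted covariates.
#' @param seed Integer seed.
#' @param nuisance_loadings Named numeric vector of loadings of planted
#'   covariates on `gender` and z-scored `age`.
#' @return A `data.frame` (class `covariate_table`) with one row per
#'   participant; the planted design is attached as attribute `"planted"`.
#' @export
simulate_covariates <- function(metrics, planted = list(), noise_sd = 0.5,
                                seed = 1L,
                                nuisance_loadings = c(gender = 0.2, age = 0.2)) {
  stopifnot(is.data.frame(metrics), "participant_id" %in% names(metrics))
  n <- nrow(metrics)
  for (pl in planted) {
    if (!pl$metric %in% names(metrics)) {
      stop("planted metric not found in metrics table: ", pl$metric)
    }
  }

  cont <- c(age = NA, BMI = NA, SBP = NA, DBP = NA, HbA1c = NA,
            glucose = NA, HOMA_IR = NA, insulin = NA,
            WMH = NA, GM = NA, WM = NA,
            global_cognition = NA, digit_span = NA, logical_memory_II = NA,
            digit_coding = NA, vocabulary = NA, word_reading = NA)
  scales <- list(
    age = c(48, 5), BMI = c(30, 6), SBP = c(122, 14), DBP = c(80, 9),
    HbA1c = c(5.6, 0.9), glucose = c(98, 25), HOMA_IR = c(3.5, 3),
    insulin = c(14, 10), WMH = c(0.15, 0.2), GM = c(44, 3), WM = c(33, 3),
    global_cognition = c(0, 1), digit_span = c(16, 4),
    logical_memory_II = c(25, 7), digit_coding = c(60, 15),
    vocabulary = c(30, 10), word_reading = c(40, 8))
  binaries <- c("gender", "race", "smoking", "drinking", "APOE4")

  with_seed(seed, {
    tab <- data.frame(participant_id = metrics$participant_id,
                      stringsAsFactors = FALSE)
    for (b in binaries) {
      latent <- stats::rnorm(n)
      tab[[b]] <- as.integer(latent > stats::median(latent))
    }
    for (nm in names(cont)) {
      sc <- scales[[nm]]
      tab[[nm]] <- stats::rnorm(n, mean = sc[1], sd = sc[2])
    }
    zage <- as.numeric(scale(tab$age))
    truth <- data.frame(covariate = character(), metric = character(),
                        beta = numeric())
    for (pl in planted) {
      zm <- as.numeric(scale(metrics[[pl$metric]]))
      tab[[pl$covariate]] <-
        pl$beta * zm +
        nuisance_loadings[["gender"]] * tab$gender +
        nuisance_loadings[["age"]] * zage +
        stats::rnorm(n, sd = noise_sd)
      truth <- rbind(truth, data.frame(covariate = pl$covariate,
                                       metric = pl$metric, beta = pl$beta))
    }
    attr(tab, "planted") <- truth
    class(tab) <- c("covariate_table", "data.frame")
    tab
  })
}
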