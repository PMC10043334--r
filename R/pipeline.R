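# End-to-end orchestration: simulate -> EC + FC -> metrics -> associations,
# with plain-text artifacts (CSV/JSON) and full determinism under a fixed
# configuration.

#' Example planted causal system
#'
#' A 6-region system with five directed couplings of mixed functional form
#' (linear, sigmoid, quadratic, threshold), strengths 0.6-0.8 at lag 1 —
#' strong enough to be recoverable from a modest cohort while passing the
#' stationarity check.
#'
#' @param n_rois Number of regions (>= 3; couplings whose endpoints exceed
#'   `n_rois` are dropped, so 6+ regions carry all five).
#' @return A [causal_system()].
#' @export
example_system <- function(n_rois = 6L) {
  if (n_rois < 3) stop("example_system needs at least 3 regions")
  edges <- data.frame(
    source = c(1L, 1L, 2L, 4L, 5L),
    target = c(2L, 3L, 4L, 5L, 6L),
    kind = c("linear", "sigmoid", "quadratic", "sigmoid", "threshold"),
    strength = c(0.8, 0.7, 0.6, 0.7, 0.8),
    lag = 1L)
  edges <- edges[edges$source <= n_rois & edges$target <= n_rois, ]
  causal_system(n_rois, edges, noise_sd = 1, self_decay = 0.3)
}

#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run; serialized verbatim into the
#' output directory so a run can be reproduced exactly.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_rois,n_participants,n_timepoints Cohort dimensions.
#' @param between_subject_sd Coupling-strength jitter across participants.
#' @param k Cross-validation folds for the EC stage.
#' @param alpha_edge Edge-wise significance level (EC and FC).
#' @param alpha_assoc Significance level of the association screen.
#' @param stages Named logical vector toggling `ec`, `fc`, `metrics`,
#'   `associations`.
#' @param ec_individual Also estimate per-participant EC graphs (needed for
#'   EC metrics and associations).
#' @param n_null,n_rewire Null-model settings for small-worldness.
#' @param planted Planted covariate associations passed to
#'   [simulate_covariates()].
#' @param dsn Optional [dsn_config()] overriding the EC training defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 7L, n_rois = 6L, n_participants = 20L,
                       n_timepoints = 200L, between_subject_sd = 0.1,
                       k = 5L, alpha_edge = 0.05, alpha_assoc = 0.05,
                       stages = c(ec = TRUE, fc = TRUE, metrics = TRUE,
                                  associations = TRUE),
                       ec_individual = TRUE, n_null = 50L, n_rewire = 10L,
                       planted = list(
                         list(covariate = "SBP",
                              metric = "characteristic_path_length",
                              beta = 0.5)),
                       dsn = NULL) {
  cfg <- list(seed = as.integer(seed), n_rois = as.integer(n_rois),
              n_participants = as.integer(n_participants),
              n_timepoints = as.integer(n_timepoints),
              between_subject_sd = between_subject_sd, k = as.integer(k),
              alpha_edge = alpha_edge, alpha_assoc = alpha_assoc,
              stages = as.list(stages), ec_individual = ec_individual,
              n_null = as.integer(n_null), n_rewire = as.integer(n_rewire),
              planted = planted, dsn = dsn)
  class(cfg) <- "run_config"
  cfg
}

write_csv_plain <- function(x, path) {
  utils::write.csv(format(as.data.frame(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Write a cohort to a directory of plain-text files
#'
#' One CSV per participant (columns = region labels, rows = timepoints), a
#' JSON manifest (ids, sampling interval, seed, system description) and a
#' ground-truth edge list CSV.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_ts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in cohort$participant_ids) {
    utils::write.csv(as.data.frame(cohort$series[[id]]),
                     file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  }
  sys <- cohort$system
  manifest <- list(participant_ids = cohort$participant_ids,
                   sampling_interval = cohort$sampling_interval,
                   seed = cohort$seed,
                   n_rois = sys$n_rois, roi_labels = sys$roi_labels,
                   noise_sd = sys$noise_sd, self_decay = sys$self_decay)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(sys$edges, file.path(dir, "ground_truth_edges.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing per-participant CSVs and
#'   `manifest.json`.
#' @return A `cohort_ts` (its `system` carries the ground-truth edges when
#'   `ground_truth_edges.csv` is present).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ids <- manifest$participant_ids
  series <- lapply(ids, function(id) {
    as.matrix(utils::read.csv(file.path(dir, paste0(id, ".csv"))))
  })
  names(series) <- ids
  gt_path <- file.path(dir, "ground_truth_edges.csv")
  edges <- if (file.exists(gt_path)) utils::read.csv(gt_path) else NULL
  if (!is.null(edges) && nrow(edges) == 0) edges <- NULL
  sys <- causal_system(manifest$n_rois, edges,
                       noise_sd = manifest$noise_sd %||% 1,
                       self_decay = manifest$self_decay %||% 0.3,
                       roi_labels = manifest$roi_labels,
                       check_stationary = FALSE)
  structure(list(participant_ids = ids, series = series,
                 sampling_interval = manifest$sampling_interval,
                 system = sys, strengths = NULL,
                 seed = manifest$seed %||% NA_integer_),
            class = "cohort_ts")
}

write_graph_files <- function(graph, dir, stem) {
  utils::write.csv(as.data.frame(graph$weights),
                   file.path(dir, paste0(stem, "_adjacency.csv")),
                   row.names = FALSE)
  if (!is.null(graph$edges)) {
    utils::write.csv(graph$edges,
                     file.path(dir, paste0(stem, "_edges.csv")),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, estimates effective connectivity (group
#' level, optionally per participant), functional connectivity (individual
#' graphs + group consensus), computes the ten-metric battery per
#' participant graph, simulates a covariate table with planted effects, and
#' screens metric-covariate associations. All artifacts are plain CSV/JSON
#' under `out_dir`; re-running with an identical config reproduces them
#' byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param cohort Optional pre-built cohort (skips simulation).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir, cohort = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- config$stages

  cfg_json <- config
  cfg_json$dsn <- if (is.null(config$dsn)) NULL else unclass(config$dsn)
  jsonlite::write_json(unclass(cfg_json), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  say("stage simulate: %d participants, %d x %d", config$n_participants,
      config$n_timepoints, config$n_rois)
  if (is.null(cohort)) {
    system <- example_system(config$n_rois)
    cohort <- simulate_cohort(system, config$n_participants,
                              config$n_timepoints,
                              between_subject_sd = config$between_subject_sd,
                              seed = config$seed)
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))

  dsn <- config$dsn %||% dsn_config(k = config$k,
                                    seed = mix_seed(config$seed, 11L))
  results <- list(cohort = cohort, config = config)

  if (isTRUE(stages$ec)) {
    say("stage ec: group graph (%d folds, %d directed pairs)",
        dsn$k, config$n_rois * (config$n_rois - 1))
    ec_dir <- file.path(out_dir, "ec")
    dir.create(ec_dir, showWarnings = FALSE)
    group_ec <- group_ec_graph(cohort, dsn, alpha = config$alpha_edge)
    write_graph_files(group_ec, ec_dir, "group")
    results$group_ec <- group_ec
    if (isTRUE(config$ec_individual)) {
      ind_ec <- vector("list", length(cohort$participant_ids))
      names(ind_ec) <- cohort$participant_ids
      for (id in cohort$participant_ids) {
        say("stage ec: individual graph %s", id)
        ind_ec[[id]] <- individual_ec_graph(cohort, id, dsn,
                                            alpha = config$alpha_edge)
        write_graph_files(ind_ec[[id]], ec_dir, paste0("individual_", id))
      }
      results$individual_ec <- ind_ec
    }
  }

  if (isTRUE(stages$fc)) {
    say("stage fc: individual graphs + consensus")
    fc_dir <- file.path(out_dir, "fc")
    dir.create(fc_dir, showWarnings = FALSE)
    ind_fc <- lapply(cohort$series, individual_fc_graph,
                     alpha = config$alpha_edge)
    for (id in names(ind_fc)) {
      write_graph_files(ind_fc[[id]], fc_dir, paste0("individual_", id))
    }
    consensus <- group_consensus_fc(ind_fc)
    write_graph_files(consensus, fc_dir, "consensus")
    results$individual_fc <- ind_fc
    results$consensus_fc <- consensus
  }

  metric_tables <- list()
  if (isTRUE(stages$metrics)) {
    if (!is.null(results$individual_ec)) {
      say("stage metrics: EC graphs")
      metric_tables$EC <- cohort_metric_table(
        results$individual_ec, n_null = config$n_null,
        n_rewire = config$n_rewire, seed = mix_seed(config$seed, 21L))
    }
    if (!is.null(results$individual_fc)) {
      say("stage metrics: FC graphs")
      metric_tables$FC <- cohort_metric_table(
        results$individual_fc, n_null = config$n_null,
        n_rewire = config$n_rewire, seed = mix_seed(config$seed, 22L))
    }
    tidy <- do.call(rbind, lapply(names(metric_tables), function(tp) {
      tab <- metric_tables[[tp]]
      long <- utils::stack(tab[, setdiff(names(tab), "participant_id")])
      data.frame(participant_id = rep(tab$participant_id,
                                      ncol(tab) - 1L),
                 graph_type = tp, metric = as.character(long$ind),
                 value = long$values, stringsAsFactors = FALSE)
    }))
    if (!is.null(tidy)) write_csv_plain(tidy, file.path(out_dir, "metrics.csv"))
    results$metrics <- metric_tables
  }

  if (isTRUE(stages$associations) && length(metric_tables)) {
    say("stage associations")
    tab <- metric_tables[[1]]
    covs <- simulate_covariates(tab, planted = config$planted,
                                seed = mix_seed(config$seed, 31L))
    predictors <- c("BMI", "SBP", "DBP", "APOE4", "HbA1c", "glucose",
                    "HOMA_IR", "insulin", "WMH", "GM", "WM",
                    "global_cognition", "digit_span", "logical_memory_II",
                    "digit_coding", "vocabulary", "word_reading")
    screen <- run_association_screen(tab, covs, predictors,
                                     alpha = config$alpha_assoc)
    write_csv_plain(covs, file.path(out_dir, "covariates.csv"))
    write_csv_plain(as.data.frame(screen),
                    file.path(out_dir, "associations.csv"))
    results$covariates <- covs
    results$associations <- screen
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gcconnect")),
    config_hash = mix_seed(config$seed, config$n_rois,
                           config$n_participants, config$n_timepoints,
                           config$k),
    stages_run = names(Filter(isTRUE, stages)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %s", out_dir)
  invisible(results)
}
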