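#' Covariate-adjusted linear association between a metric and a predictor
#'
#' Ordinary least squares of one outcome on an intercept, a set of nuisance
#' covariates (by default gender, race and age) and one predictor of
#' interest, on complete cases. Returns the predictor's coefficient,
#' standard error and two-tailed p value. The outcome is normally a graph
#' metric and the predictor a participant characteristic, but any column of
#' the merged metric + covariate table may play either role.
#'
#' @param metrics `data.frame` with `participant_id` and metric columns
#'   (may be `NULL` if `covariates` already contains the outcome).
#' @param covariates `data.frame` with `participant_id` and covariate
#'   columns.
#' @param outcome,predictor Column names in the merged table.
#' @param nuisance Character vector of nuisance covariate names (fixed in
#'   every model); may be empty.
#' @param standardize One of `"none"` (default: raw scales), `"outcome"`,
#'   `"predictor"`, `"both"` — z-score the named variables before fitting.
#' @param min_n Minimum number of complete cases (default 10).
#' @return One-row `data.frame`: `metric`, `predictor`, `beta`, `se`, `p`,
#'   `n`, `covariates_used`.
#' @export
fit_association <- function(metrics, covariates, outcome, predictor,
                            nuisance = c("gender", "race", "age"),
                            standardize = c("none", "outcome", "predictor",
                                            "both"),
                            min_n = 10L) {
  standardize <- match.arg(standardize)
  if (predictor %in% nuisance) {
    stop("the predictor must not also be a nuisance covariate")
  }
  df <- merge_assoc_tables(metrics, covariates)
  for (v in c(outcome, predictor, nuisance)) {
    if (!v %in% names(df)) stop("column not found: ", v)
  }
  use <- stats::complete.cases(df[, c(outcome, predictor, nuisance)])
  df <- df[use, , drop = FALSE]
  n <- nrow(df)
  if (n < min_n) stop("fewer than ", min_n, " complete cases")
  if (standardize %in% c("outcome", "both")) {
    df[[outcome]] <- as.numeric(scale(df[[outcome]]))
  }
  if (standardize %in% c("predictor", "both")) {
    df[[predictor]] <- as.numeric(scale(df[[predictor]]))
  }
  rhs <- paste(c(nuisance, predictor), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::lm(fml, data = df)
  co <- summary(fit)$coefficients
  if (!predictor %in% rownames(co)) {
    stop("rank-deficient design: predictor `", predictor,
         "` is collinear with the nuisance covariates")
  }
  data.frame(metric = outcome, predictor = predictor,
             beta = co[predictor, "Estimate"],
             se = co[predictor, "Std. Error"],
             p = co[predictor, "Pr(>|t|)"],
             n = n,
             covariates_used = paste(nuisance, collapse = ";"),
             stringsAsFactors = FALSE)
}

merge_assoc_tables <- function(metrics, covariates) {
  if (is.null(metrics)) return(as.data.frame(covariates))
  stopifnot("participant_id" %in% names(metrics),
            "participant_id" %in% names(covariates))
  merge(as.data.frame(metrics), as.data.frame(covariates),
        by = "participant_id")
}

#' Screen all metric x predictor pairs with covariate-adjusted models
#'
#' One linear model per (metric, predictor) pair — outcome the metric,
#' regressors the fixed nuisance covariates plus the single predictor —
#' flagged significant at `alpha`. No correction across tests by default
#' (each pair tested at `alpha`); Benjamini-Hochberg correction is applied
#' when `fdr = TRUE`.
#'
#' @inheritParams fit_association
#' @param predictors Character vector of predictor column names (non-empty).
#' @param metric_names Metric columns to use as outcomes; defaults to every
#'   non-id column of `metrics`.
#' @param alpha Significance level for flagging.
#' @param fdr Apply BH correction across all tests before flagging.
#' @return `data.frame` of class `assoc_screen`: one row per pair with
#'   `beta`, `se`, `p`, `n` and `significant`.
#' @export
run_association_screen <- function(metrics, covariates, predictors,
                                   alpha = 0.05,
                                   nuisance = c("gender", "race", "age"),
                                   metric_names = NULL, fdr = FALSE,
                                   min_n = 10L) {
  if (!length(predictors)) stop("empty predictor list")
  for (p in predictors) {
    if (!p %in% names(covariates)) stop("predictor not in covariate table: ", p)
  }
  if (is.null(metric_names)) {
    metric_names <- setdiff(names(metrics), "participant_id")
  }
  rows <- list()
  for (m in metric_names) {
    for (p in predictors) {
      rows[[length(rows) + 1L]] <- tryCatch(
        fit_association(metrics, covariates, m, p, nuisance = nuisance,
                        min_n = min_n),
        error = function(e) {
          data.frame(metric = m, predictor = p, beta = NA_real_,
                     se = NA_real_, p = NA_real_, n = NA_integer_,
                     covariates_used = paste(nuisance, collapse = ";"),
                     stringsAsFactors = FALSE)
        })
    }
  }
  out <- do.call(rbind, rows)
  p_use <- if (fdr) stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(p_use) & p_use < alpha
  class(out) <- c("assoc_screen", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "fdr") <- fdr
  out
}

#' @export
print.assoc_screen <- function(x, ...) {
  cat(sprintf("Association screen: %d models, %d significant at alpha = %g%s\n",
              nrow(x), sum(x$significant, na.rm = TRUE), attr(x, "alpha"),
              if (isTRUE(attr(x, "fdr"))) " (BH-corrected)" else ""))
  sig <- x[which(x$significant), , drop = FALSE]
  if (nrow(sig)) {
    print.data.frame(sig[order(sig$p), ], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
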