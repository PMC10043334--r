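make_assoc_tables <- function(n = 100, seed = 1) {
  set.seed(seed)
  metrics <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                        degree = rnorm(n, 280, 20),
                        characteristic_path_length = rnorm(n, 1.5, 0.1))
  covs <- data.frame(participant_id = metrics$participant_id,
                     gender = rbinom(n, 1, 0.5),
                     race = rbinom(n, 1, 0.5),
                     age = rnorm(n, 48, 5),
                     SBP = rnorm(n, 122, 14))
  list(metrics = metrics, covs = covs)
}

test_that("an exact linear relationship is recovered exactly", {
  tt <- make_assoc_tables()
  tt$metrics$degree <- 2 * tt$covs$SBP
  res <- suppressWarnings(  # lm warns on an essentially perfect fit
    fit_association(tt$metrics, tt$covs, "degree", "SBP"))
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_lt(res$p, 1e-20)
  expect_equal(res$n, 100)
  expect_equal(res$covariates_used, "gender;race;age")
})

test_that("type-I error of the adjusted model sits at the nominal level", {
  hits <- vapply(seq_len(1000), function(s) {
    tt <- make_assoc_tables(n = 100, seed = 2000 + s)
    fit_association(tt$metrics, tt$covs, "degree", "SBP")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("shifting the outcome by a constant changes nothing but the intercept", {
  tt <- make_assoc_tables(seed = 5)
  r1 <- fit_association(tt$metrics, tt$covs, "degree", "SBP")
  tt$metrics$degree <- tt$metrics$degree + 1000
  r2 <- fit_association(tt$metrics, tt$covs, "degree", "SBP")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("degenerate designs and thin data are rejected", {
  tt <- make_assoc_tables()
  tt$covs$SBP2 <- tt$covs$gender  # collinear with a nuisance covariate
  expect_error(fit_association(tt$metrics, tt$covs, "degree", "SBP2"),
               "collinear|rank")
  expect_error(fit_association(tt$metrics, tt$covs, "degree", "gender"),
               "nuisance")
  expect_error(fit_association(tt$metrics[1:5, ], tt$covs[1:5, ],
                               "degree", "SBP"), "complete cases")
  expect_error(fit_association(tt$metrics, tt$covs, "degree", "nope"),
               "not found")
})

test_that("planted effects are covered by their confidence intervals", {
  covered <- vapply(seq_len(200), function(s) {
    set.seed(s)
    n <- 100
    metrics <- data.frame(participant_id = seq_len(n),
                          characteristic_path_length = rnorm(n, 1.5, 0.1))
    covs <- simulate_covariates(
      metrics,
      planted = list(list(covariate = "SBP",
                          metric = "characteristic_path_length",
                          beta = 0.5)),
      noise_sd = 0.5, seed = 10000 + s)
    covs$cpl_z <- as.numeric(scale(metrics$characteristic_path_length))
    res <- fit_association(NULL, covs, "SBP", "cpl_z",
                           nuisance = c("gender", "age"))
    abs(res$beta - 0.5) < qt(0.975, res$n - 4) * res$se
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
})

test_that("the screen flags about alpha of tests under the global null", {
  set.seed(77)
  n <- 100
  metrics <- data.frame(participant_id = seq_len(n))
  for (m in paste0("metric_", 1:10)) metrics[[m]] <- rnorm(n)
  covs <- data.frame(participant_id = seq_len(n),
                     gender = rbinom(n, 1, 0.5), race = rbinom(n, 1, 0.5),
                     age = rnorm(n, 48, 5))
  for (p in paste0("pred_", 1:20)) covs[[p]] <- rnorm(n)
  scr <- run_association_screen(metrics, covs, paste0("pred_", 1:20),
                                alpha = 0.05)
  expect_equal(nrow(scr), 200)
  expect_lte(sum(scr$significant), 25)  # ~10 expected, binomial slack
  expect_gte(sum(scr$significant), 1)

  scr_fdr <- run_association_screen(metrics, covs, paste0("pred_", 1:20),
                                    alpha = 0.05, fdr = TRUE)
  expect_lte(sum(scr_fdr$significant), 2)
  expect_error(run_association_screen(metrics, covs, character(0)), "empty")
  expect_error(run_association_screen(metrics, covs, "nope"),
               "not in covariate table")
})

test_that("the screen uses the fixed demographic nuisance design", {
  tt <- make_assoc_tables(seed = 9)
  scr <- run_association_screen(tt$metrics, tt$covs, "SBP")
  expect_true(all(scr$covariates_used == "gender;race;age"))
  expect_equal(nrow(scr), 2)  # two metrics x one predictor
  direct <- fit_association(tt$metrics, tt$covs, "degree", "SBP")
  expect_equal(scr$beta[scr$metric == "degree"], direct$beta)
})
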