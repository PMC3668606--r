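test_that("classifier resolves auto gamma and separates separable data", {
  set.seed(51)
  x <- matrix(stats::rnorm(60 * 6), 60, 6)
  y <- rep(c(TRUE, FALSE), each = 30)
  x[y, 1] <- x[y, 1] + 10  # well separated in one coordinate
  m <- train_classifier(x, y)
  expect_equal(m$gamma, 1 / 6)  # reciprocal of the number of input features
  expect_equal(m$spec$C, 100)
  pred <- predict(m, x)
  expect_equal(unname(pred == "positive"), y)  # perfect resubstitution
  # retraining on identical data reproduces identical predictions
  set.seed(99); probe <- matrix(stats::rnorm(20 * 6), 20, 6)
  m2 <- train_classifier(x, y)
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_error(train_classifier(x, rep(TRUE, 60)), class = "nbs_training_error")
})

test_that("evaluate_subset scores a planted marker near-perfectly", {
  cfg <- pku_config(8000, prevalence = 4e-3, band = 8e-3, seed = 5)
  sim <- simulate_cohort(cfg)
  tri <- triage(sim$cohort, default_diseases()$pku)
  flagged <- which(tri != "negative")
  pool <- sim$cohort[flagged]
  lab <- pool$confirmed == "diseased"
  split <- nbscreen:::stratified_split(lab, 0.3, seed = 1)
  phe <- list(feature_spec("raw", "Phe"))
  ss <- evaluate_subset(phe, pool[split$train], lab[split$train],
                        pool[split$eval], lab[split$eval])
  expect_equal(ss[["sensitivity"]], 100)
  expect_gt(ss[["specificity"]], 90)
  # a pure-noise feature cannot beat the planted marker's separation
  noise <- list(feature_spec("raw", "C12"))
  ss_noise <- evaluate_subset(noise, pool[split$train], lab[split$train],
                              pool[split$eval], lab[split$eval])
  expect_lt(min(ss_noise, na.rm = TRUE), 100)
  expect_error(evaluate_subset(list(), pool, lab, pool, lab),
               class = "nbs_config_error")
})

test_that("subset search enumerates 2^K - 1 subsets and matches brute force", {
  cfg <- pku_config(6000, prevalence = 4e-3, band = 8e-3, seed = 7)
  sim <- simulate_cohort(cfg)
  pool <- sim$cohort[triage(sim$cohort, default_diseases()$pku) != "negative"]
  lab <- pool$confirmed == "diseased"
  raw <- lapply(as.character(pool$panel), function(a) feature_spec("raw", a))
  rk <- rank_features(pool, lab, raw, top = 8)
  split <- nbscreen:::stratified_split(lab, 0.25, seed = 2)
  K <- 6
  res <- search_optimal_subset(rk, pool[split$train], lab[split$train],
                               pool[split$eval], lab[split$eval], max_rank = K)
  expect_equal(nrow(res$ledger), 2^K - 1)
  expect_true(all(res$ledger$sensitivity >= 0 & res$ledger$sensitivity <= 100,
                  na.rm = TRUE))
  expect_true(all(res$ledger$specificity >= 0 & res$ledger$specificity <= 100,
                  na.rm = TRUE))
  # independent brute-force re-enumeration agrees on metrics and winner
  oracle <- brute_search(rk, K, pool[split$train], lab[split$train],
                         pool[split$eval], lab[split$eval])
  expect_equal(vapply(oracle$rows, `[[`, numeric(1), "sens"),
               res$ledger$sensitivity)
  expect_equal(vapply(oracle$rows, `[[`, numeric(1), "spec"),
               res$ledger$specificity)
  expect_equal(oracle$best$i, res$winner_index)
  # winner row satisfies the selection invariant
  row <- res$ledger[res$winner_index, ]
  expect_equal(row$sensitivity, 100)
  ok <- res$ledger$sensitivity == 100
  expect_gte(row$specificity, max(res$ledger$specificity[ok]))
})

test_that("subset search handles K = 1, separating singletons, and no-winner", {
  p <- analyte_panel(c("A", "B"))
  set.seed(61)
  n <- 30
  vals <- matrix(stats::rlnorm(n * 2, 1, 0.3), n, 2)
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  vals[lab, 1] <- vals[lab, 1] * 100  # A separates perfectly, B is noise
  co <- mat_cohort(vals, p)
  cands <- list(feature_spec("raw", "A"), feature_spec("raw", "B"))
  rk <- rank_features(co, lab, cands, top = 2)
  split <- nbscreen:::stratified_split(lab, 0.3, seed = 3)
  res1 <- search_optimal_subset(rk, co[split$train], lab[split$train],
                                co[split$eval], lab[split$eval], max_rank = 1)
  expect_equal(nrow(res1$ledger), 1L)
  res2 <- search_optimal_subset(rk, co[split$train], lab[split$train],
                                co[split$eval], lab[split$eval], max_rank = 2)
  expect_length(res2$winner, 1L)  # fewest-features tie-break picks singleton
  expect_equal(res2$winner[[1]]$display, "A")
  # constant features cannot separate a rare positive class:
  # explicit no-winner result, ledger intact
  const <- mat_cohort(matrix(1, n, 2), p)
  labc <- rep(c(TRUE, FALSE), c(5, 25))
  splitc <- nbscreen:::stratified_split(labc, 0.3, seed = 3)
  rkc <- structure(data.frame(feature = c("A", "B"), f_score = c(0, 0)),
                   specs = cands, class = c("ranked_features", "data.frame"))
  res3 <- search_optimal_subset(rkc, const[splitc$train], labc[splitc$train],
                                const[splitc$eval], labc[splitc$eval], max_rank = 2)
  expect_null(res3$winner)
  expect_equal(nrow(res3$ledger), 3L)
  # full-scale enumeration (> 15 available features) requires an explicit flag
  many <- lapply(paste0("F", 1:16), function(a) feature_spec("raw", a))
  rk16 <- structure(data.frame(feature = paste0("F", 1:16), f_score = 16:1),
                    specs = many, class = c("ranked_features", "data.frame"))
  expect_error(search_optimal_subset(rk16, co, lab, co, lab, max_rank = 16),
               class = "nbs_config_error")
})

test_that("cross-validation stratifies, is seeded, and applies tie-breaks", {
  p <- analyte_panel(c("A", "B"))
  set.seed(71)
  vals <- matrix(stats::rlnorm(20 * 2, 1, 0.2), 20, 2)
  lab <- rep(c(TRUE, FALSE), each = 10)
  vals[lab, 1] <- vals[lab, 1] * 100
  co <- mat_cohort(vals, p)
  subset <- list(feature_spec("raw", "A"))
  # 10 + 10 records in 5 folds: every fold holds out exactly 2 per class
  asg <- nbscreen:::stratified_folds(lab, 5, seed = 0)
  for (f in 1:5) {
    expect_equal(sum(asg == f & lab), 2L)
    expect_equal(sum(asg == f & !lab), 2L)
  }
  m <- crossvalidate_optimal_model(subset, co, lab, folds = 5, seed = 0)
  # separable data: every fold ties at 100/100 and fold 1 wins
  expect_true(all(m$cv_table$sensitivity == 100))
  expect_true(all(m$cv_table$specificity == 100))
  expect_equal(m$fingerprint$selected_fold, 1L)
  # same seed -> identical fold assignment and fingerprint
  m2 <- crossvalidate_optimal_model(subset, co, lab, folds = 5, seed = 0)
  expect_identical(m$cv_table, m2$cv_table)
  expect_identical(m$fingerprint, m2$fingerprint)
  # class smaller than fold count is a configuration error
  expect_error(crossvalidate_optimal_model(subset, co[1:12], lab[1:12],
                                           folds = 5, seed = 0),
               class = "nbs_config_error")
})
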