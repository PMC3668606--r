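test_that("confusion cross-tabulation conserves the cohort and flags unknowns", {
  truth <- c(rep("diseased", 3), rep("not_diseased", 7))
  perfect <- c(rep(TRUE, 3), rep(FALSE, 7))
  cc <- confusion(perfect, truth)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 3L, TN = 7L, FP = 0L, FN = 0L))
  all_neg <- confusion(rep(FALSE, 10), truth)
  expect_equal(all_neg$FN, 3L)
  expect_equal(all_neg$TN, 7L)
  # conservation on random inputs
  set.seed(81)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    pr <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tr <- sample(c("diseased", "not_diseased"), n, replace = TRUE)
    cc <- confusion(pr, tr)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
  }
  err <- expect_error(
    confusion(data.frame(sample_id = c("a", "b"), flagged = TRUE,
                         screen_positive = c(TRUE, FALSE)),
              c("diseased", "unknown")),
    class = "nbs_value_error")
  expect_match(conditionMessage(err), "b")
})

test_that("screening metrics reproduce the published 2011 prediction rows", {
  # proposed-method rows: counts -> 3-decimal percentages
  pku <- metrics_from_confusion(confusion_counts(3, 72111, 2, 0))
  expect_equal(unname(format(pku)), c("100.000", "99.997", "99.997"))
  mcc <- metrics_from_confusion(confusion_counts(6, 72255, 46, 0))
  expect_equal(format(mcc)[["specificity"]], "99.936")
  hyp <- metrics_from_confusion(confusion_counts(3, 72112, 10, 0))
  expect_equal(format(hyp)[["specificity"]], "99.986")
  # undefined denominators are not-applicable, never 0
  none <- metrics_from_confusion(confusion_counts(0, 5, 1, 0))
  expect_true(is.na(none$sensitivity))
  expect_equal(format(none)[["sensitivity"]], "—")
  # full-precision values agree with direct recomputation
  expect_equal(pku$specificity, 100 * 72111 / (72111 + 2))
  set.seed(82)
  for (i in 1:10) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:500, 1),
                           sample(0:50, 1), sample(0:50, 1))
    m <- metrics_from_confusion(cc)
    if (!is.na(m$accuracy)) {
      expect_equal(m$accuracy,
                   100 * (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN))
    }
  }
})

test_that("the current method's unpublished cells are recoverable", {
  cur <- derive_current_confusion(confusion_counts(3, 72111, 2, 0), 21)
  expect_equal(cur$TN, 72092L)
  expect_equal(format(metrics_from_confusion(cur))[["specificity"]], "99.971")
})

test_that("two-stage prediction never calls a below-cutoff record positive", {
  cfg <- pku_config(4000, prevalence = 5e-3, band = 8e-3, seed = 15)
  sim <- simulate_cohort(cfg)
  pku <- default_diseases()$pku
  pool <- sim$cohort[triage(sim$cohort, pku) != "negative"]
  lab <- pool$confirmed == "diseased"
  model <- train_classifier(evaluate_features(pool, list(feature_spec("raw", "Phe"))),
                            lab, features = list(feature_spec("raw", "Phe")))
  pred <- two_stage_predict(sim$cohort, pku, model)
  expect_equal(nrow(pred), n_records(sim$cohort))
  # stage-1 guarantee
  expect_false(any(pred$screen_positive[!pred$flagged]))
  expect_identical(pred$flagged,
                   unname(sim$cohort$values[, "Phe"] >= pku$screening_cutoff))
  # a cohort entirely below the cutoff yields zero screen positives
  low <- sim$cohort[sim$cohort$values[, "Phe"] < pku$screening_cutoff]
  pred_low <- two_stage_predict(low, pku, model)
  expect_equal(sum(pred_low$screen_positive), 0L)
  # planted cases are recovered as screen positives
  cases <- sim$status == "case:PKU"
  expect_true(all(pred$screen_positive[cases]))
})

test_that("cutoff baseline counts the suspected band as false positives", {
  p <- analyte_panel(c("Phe", "Met"))
  pku <- default_diseases()$pku
  # 3 diseased above the diagnostic cutoff, 4 healthy in the band, 5 clean
  phe <- c(300, 400, 250, 100, 150, 90, 200, 50, 60, 70, 40, 30)
  truth <- c(rep("diseased", 3), rep("not_diseased", 9))
  co <- mat_cohort(cbind(Phe = phe, Met = 20), p, confirmed = truth)
  cc <- baseline_current_method(triage(co, pku), truth)
  expect_equal(cc$TP, 3L)
  expect_equal(cc$FP, 4L)
  expect_equal(cc$TN, 5L)
  expect_equal(cc$FN, 0L)
  # no suspected band -> no false positives
  co2 <- mat_cohort(cbind(Phe = c(300, 50, 60), Met = 20), p,
                    confirmed = c("diseased", rep("not_diseased", 2)))
  expect_equal(baseline_current_method(triage(co2, pku), co2$confirmed)$FP, 0L)
})

test_that("comparison reports render and round-trip losslessly", {
  cur <- confusion_counts(3, 72092, 21, 0)
  prop <- confusion_counts(3, 72111, 2, 0)
  rep_ <- comparison_report(cur, prop, default_diseases()$pku)
  expect_equal(nrow(rep_), 2L)
  out <- capture.output(print(rep_))
  expect_true(any(grepl("99.997", out)))
  expect_true(any(grepl("99.971", out)))
  # identical inputs give a zero-difference report
  same <- comparison_report(prop, prop, "PKU")
  expect_equal(same$specificity[1], same$specificity[2])
  # CSV round trip preserves full precision
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(rep_, path)
  back <- read_comparison_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rep_))
  # undefined metrics survive the round trip as NA
  odd <- comparison_report(confusion_counts(0, 10, 0, 0), prop, "x")
  write_comparison_csv(odd, path)
  expect_true(is.na(read_comparison_csv(path)$sensitivity[1]))
})
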