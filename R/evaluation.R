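#' Two-stage screening prediction
#'
#' Stage 1 is the cutoff triage: records strictly below the disease's
#' screening cutoff are screen-negative without consulting the classifier,
#' and records strictly above the diagnostic cutoff are screen-positive
#' directly — they are positive cases under the triage definition and a
#' screening programme never downgrades them, so the learned model cannot
#' lose sensitivity relative to the cutoff scheme. Stage 2 applies the
#' trained classifier to the remaining suspected band (marker between the
#' two cutoffs), which is where the cutoff scheme's false positives live.
#'
#' `classify_band_only = FALSE` sends every flagged record (at or above the
#' screening cutoff, diagnostic exceeders included) through the classifier;
#' `classify_all = TRUE` additionally bypasses the stage-1 gate entirely.
#' Both are for sensitivity analysis.
#'
#' @param cohort an `nbs_cohort`.
#' @param disease a [disease_definition()].
#' @param model an `nbs_model` whose features are computable from the panel.
#' @param classify_band_only if `TRUE` (default) diagnostic-cutoff exceeders
#'   bypass the classifier as positives.
#' @param classify_all run the classifier on every record (default `FALSE`).
#' @param eps ratio denominator guard.
#' @return a data frame with columns `sample_id`, `flagged` (logical,
#'   survived stage 1) and `screen_positive` (logical).
#' @export
two_stage_predict <- function(cohort, disease, model,
                              classify_band_only = TRUE, classify_all = FALSE,
                              eps = 1e-6) {
  stopifnot(inherits(cohort, "nbs_cohort"), inherits(disease, "disease_definition"),
            inherits(model, "nbs_model"))
  marker <- marker_values(cohort, disease)
  flagged <- marker >= disease$screening_cutoff
  over_diag <- marker > disease$diagnostic_cutoff
  consult <- if (classify_all) {
    rep(TRUE, n_records(cohort))
  } else if (classify_band_only) {
    flagged & !over_diag
  } else {
    flagged
  }
  screen_positive <- rep(FALSE, n_records(cohort))
  if (any(consult)) {
    x <- evaluate_features(cohort[consult], model$features, eps = eps)
    screen_positive[consult] <- predict(model, x) == "positive"
  }
  if (!classify_all) {
    if (classify_band_only) screen_positive[over_diag] <- TRUE
    screen_positive[!flagged] <- FALSE
  }
  data.frame(sample_id = cohort$sample_id, flagged = flagged,
             screen_positive = screen_positive, stringsAsFactors = FALSE)
}

#' Confusion counts
#'
#' Either construct counts directly or cross-tabulate predictions against
#' confirmed truth with [confusion()].
#'
#' @param TP,TN,FP,FN non-negative integer cell counts.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  cells <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_nbs("confusion cells must be non-negative integers", class = "nbs_value_error")
  }
  structure(as.list(stats::setNames(as.integer(round(cells)), names(cells))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Cross-tabulate screen predictions against confirmed truth
#'
#' Positives are the confirmed-diseased records. Truth labels must be
#' resolved (`diseased` / `not_diseased`); any `unknown` label aborts with
#' the offending sample ids, because silently treating unknowns as healthy
#' would fabricate true negatives.
#'
#' @param pred logical vector of screen-positive predictions, or the data
#'   frame from [two_stage_predict()].
#' @param truth character vector of confirmed labels, or an `nbs_cohort`
#'   (its `confirmed` field is used).
#' @return a [confusion_counts()]; cells always sum to the number of records.
#' @export
confusion <- function(pred, truth) {
  if (is.data.frame(pred)) {
    ids <- pred$sample_id
    pred <- pred$screen_positive
  } else {
    ids <- NULL
  }
  if (inherits(truth, "nbs_cohort")) {
    ids <- ids %||% truth$sample_id
    truth <- truth$confirmed
  }
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop_nbs("pred and truth must have equal length", class = "nbs_format_error")
  }
  unk <- which(!truth %in% c("diseased", "not_diseased"))
  if (length(unk)) {
    who <- if (is.null(ids)) paste("record", unk) else ids[unk]
    stop_nbs("unknown truth label for: %s",
             paste(utils::head(who, 10), collapse = ", "), class = "nbs_value_error")
  }
  d <- truth == "diseased"
  confusion_counts(TP = sum(pred & d), TN = sum(!pred & !d),
                   FP = sum(pred & !d), FN = sum(!pred & d))
}

#' Screening metrics from confusion counts
#'
#' Sensitivity `100·TP/(TP+FN)`, specificity `100·TN/(TN+FP)` and accuracy
#' `100·(TP+TN)/n`, as percentages. A zero denominator yields `NA`
#' (reported as not-applicable, never as 0). Values are kept at full
#' precision; display rounding (half-up, 3 decimals) happens only in
#' [format()] / [comparison_report()].
#'
#' @param counts a [confusion_counts()].
#' @return a `screen_metrics` object with fields `sensitivity`,
#'   `specificity`, `accuracy` and the originating `counts`.
#' @examples
#' m <- metrics_from_confusion(confusion_counts(3, 72111, 2, 0))
#' format(m)  # "100.000" "99.997" "99.997"
#' @export
metrics_from_confusion <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  structure(list(
    sensitivity = rate(counts$TP, counts$TP + counts$FN),
    specificity = rate(counts$TN, counts$TN + counts$FP),
    accuracy = rate(counts$TP + counts$TN, n),
    counts = counts
  ), class = "screen_metrics")
}

#' @export
format.screen_metrics <- function(x, digits = 3, na_mark = "\u2014", ...) {
  v <- c(sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy)
  out <- ifelse(is.na(v), na_mark,
                formatC(round_half_up(v, digits), format = "f", digits = digits))
  stats::setNames(out, names(v))
}

#' @export
print.screen_metrics <- function(x, ...) {
  f <- format(x)
  cat(sprintf("<screen_metrics> sensitivity %s%%, specificity %s%%, accuracy %s%%\n",
              f[["sensitivity"]], f[["specificity"]], f[["accuracy"]]))
  invisible(x)
}

#' Confusion counts of the current cutoff scheme
#'
#' The comparator baseline: the cutoff scheme calls every triage-flagged
#' record (suspected or positive) a screen positive and every below-cutoff
#' record a screen negative, so suspected non-diseased records are its false
#' positives.
#'
#' @param triage_labels factor from [triage()] / [triage_cohort()]`$labels`.
#' @param truth confirmed labels (or an `nbs_cohort`).
#' @return a [confusion_counts()].
#' @export
baseline_current_method <- function(triage_labels, truth) {
  pred <- as.character(triage_labels) %in% c("suspected", "positive")
  confusion(pred, truth)
}

#' Current-versus-proposed comparison report
#'
#' Assembles the two methods' confusion counts and derived metrics into one
#' table per disease: one row per method with TP/TN/FP/FN and
#' sensitivity/specificity/accuracy. Percentages are reported rounded
#' half-up to 3 decimals; undefined metrics print as an em-dash.
#'
#' @param current [confusion_counts()] of the cutoff scheme.
#' @param proposed [confusion_counts()] of the two-stage classifier.
#' @param disease a [disease_definition()] or disease name.
#' @return a `comparison_report` data frame.
#' @export
comparison_report <- function(current, proposed, disease) {
  name <- if (inherits(disease, "disease_definition")) disease$name else as.character(disease)
  row <- function(method, counts) {
    m <- metrics_from_confusion(counts)
    data.frame(disease = name, method = method,
               TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, stringsAsFactors = FALSE)
  }
  structure(rbind(row("current", current), row("proposed", proposed)),
            class = c("comparison_report", "data.frame"))
}

#' @export
print.comparison_report <- function(x, ...) {
  df <- as.data.frame(x)
  for (col in c("sensitivity", "specificity", "accuracy")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "\u2014",
                        formatC(round_half_up(df[[col]], 3), format = "f", digits = 3))
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write / read a comparison report as CSV
#'
#' The CSV form keeps metrics at full precision so that
#' `read_comparison_csv(write_comparison_csv(r))` round-trips losslessly.
#'
#' @param report a [comparison_report()].
#' @param path destination path.
#' @return `path` invisibly ([write_comparison_csv()]); a
#'   `comparison_report` ([read_comparison_csv()]).
#' @export
write_comparison_csv <- function(report, path) {
  df <- as.data.frame(report)
  for (col in c("sensitivity", "specificity", "accuracy")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
read_comparison_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (col in c("TP", "TN", "FP", "FN")) df[[col]] <- as.integer(df[[col]])
  for (col in c("sensitivity", "specificity", "accuracy")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  structure(df, class = c("comparison_report", "data.frame"))
}
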