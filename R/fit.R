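#' Fit a two-stage screening model for one disease
#'
#' End-to-end fitting pipeline on a training cohort:
#' \enumerate{
#'   \item cutoff triage flags the suspected and positive records; the
#'     training pool is those flagged records, with confirmed cases as the
#'     positive class and the rest as suspecteds;
#'   \item signed primary weights from class median differences
#'     ([compute_primary_weights()]), top 3 per sign ([select_signed_top()]);
#'   \item manifested features (products and ratios) over the selected
#'     markers ([build_manifested_features()]), pooled with the raw panel
#'     analytes and ranked by two-class F-score ([rank_features()]);
#'   \item exhaustive subset search over the top-ranked features with an RBF
#'     SVM, scored on a seeded stratified internal split, winner = highest
#'     specificity at 100% sensitivity ([search_optimal_subset()]);
#'   \item stratified k-fold cross-validation of the winning subset,
#'     returning the best fold model ([crossvalidate_optimal_model()]). When
#'     a class has fewer members than `folds`, the fold count is reduced to
#'     the largest feasible value (recorded in `folds_used`); with fewer
#'     than 2 per class the model is refit on the whole pool instead.
#' }
#'
#' @param cohort training `nbs_cohort`. If any confirmed labels are present
#'   they define the positive class; otherwise triage positives do.
#' @param disease a [disease_definition()].
#' @param top features kept after F-score ranking (default 20).
#' @param max_rank top-ranked features entering the exhaustive subset search
#'   (default 10; `2^max_rank - 1` classifiers are trained).
#' @param folds cross-validation folds (default 5).
#' @param split_frac held-out fraction of the internal evaluation split
#'   (default 0.2).
#' @param k_markers markers selected per weight sign (default 3).
#' @param seed integer seed driving the internal split and fold assignment.
#' @param spec a [classifier_spec()] (default C = 100, gamma = "auto").
#' @param full_search allow `max_rank > 15` (about a million fits at 20).
#' @param eps ratio denominator guard.
#' @return an object of class `nbs_screen` with components `disease`,
#'   `weights`, `markers`, `manifested`, `ranked`, `selection`, `model`,
#'   `counts`, `folds_used`, `seed`, `call`.
#' @seealso [predict.nbs_screen()], [evaluate_screen()]
#' @export
nbs_screen <- function(cohort, disease, top = 20, max_rank = 10, folds = 5,
                       split_frac = 0.2, k_markers = 3, seed = 0,
                       spec = classifier_spec(), full_search = FALSE,
                       eps = 1e-6) {
  stopifnot(inherits(cohort, "nbs_cohort"), inherits(disease, "disease_definition"))
  cl <- match.call()
  tri <- triage_cohort(cohort, disease)
  flagged_idx <- which(tri$labels != "negative")
  if (length(flagged_idx) < 4L) {
    stop_nbs("only %d records flagged by the screening cutoff; need at least 4",
             length(flagged_idx), class = "nbs_insufficient_data")
  }
  pool <- cohort[flagged_idx]
  is_pos <- if (any(pool$confirmed != "unknown")) {
    pool$confirmed == "diseased"
  } else {
    tri$labels[flagged_idx] == "positive"
  }
  if (sum(is_pos) < 2L || sum(!is_pos) < 2L) {
    stop_nbs("need at least 2 confirmed cases and 2 suspecteds among flagged records",
             class = "nbs_insufficient_data")
  }

  weights <- compute_primary_weights(pool[is_pos], pool[!is_pos])
  markers <- select_signed_top(weights, k = k_markers)
  manifested <- build_manifested_features(markers$positive, markers$negative)
  raw <- lapply(as.character(cohort$panel), function(a) feature_spec("raw", a))
  ranked <- rank_features(pool, is_pos, c(raw, manifested), top = top, eps = eps)

  split <- stratified_split(is_pos, frac = split_frac, seed = seed)
  selection <- search_optimal_subset(
    ranked, pool[split$train], is_pos[split$train],
    pool[split$eval], is_pos[split$eval],
    spec = spec, max_rank = max_rank, full_search = full_search, eps = eps)

  model <- NULL
  folds_used <- NA_integer_
  if (!is.null(selection$winner)) {
    folds_used <- min(as.integer(folds), sum(is_pos), sum(!is_pos))
    if (folds_used >= 2L) {
      model <- crossvalidate_optimal_model(selection$winner, pool, is_pos,
                                           spec = spec, folds = folds_used,
                                           seed = seed, eps = eps)
    } else {
      x <- evaluate_features(pool, selection$winner, eps = eps)
      model <- train_classifier(x, is_pos, spec, features = selection$winner,
                                fingerprint = list(seed = seed, fold = NA))
    }
  }
  structure(list(
    disease = disease, panel = cohort$panel, weights = weights,
    markers = markers, manifested = manifested, ranked = ranked,
    selection = selection, model = model,
    counts = c(flagged = length(flagged_idx), positives = sum(is_pos),
               suspecteds = sum(!is_pos)),
    folds_used = folds_used, seed = as.integer(seed), call = cl
  ), class = "nbs_screen")
}

#' @export
print.nbs_screen <- function(x, ...) {
  cat(sprintf("Two-stage screening model for %s (marker %s)\n",
              x$disease$name, x$disease$marker))
  cat(sprintf("  training pool: %d flagged (%d confirmed cases, %d suspecteds)\n",
              x$counts[["flagged"]], x$counts[["positives"]], x$counts[["suspecteds"]]))
  cat(sprintf("  markers: + %s | - %s\n",
              paste(x$markers$positive, collapse = ", "),
              paste(x$markers$negative, collapse = ", ")))
  if (is.null(x$selection$winner)) {
    cat("  no feature subset reached 100% sensitivity on the internal split\n")
  } else {
    row <- x$selection$ledger[x$selection$winner_index, ]
    cat(sprintf("  optimal features: %s\n", row$features))
    cat(sprintf("  internal split: sensitivity %.1f%%, specificity %.1f%%\n",
                row$sensitivity, row$specificity))
  }
  invisible(x)
}

#' @export
summary.nbs_screen <- function(object, n_ledger = 5, ...) {
  print(object)
  cat("\nTop ranked features (F-score):\n")
  print(utils::head(as.data.frame(object$ranked), 10), row.names = FALSE)
  led <- object$selection$ledger
  led <- led[order(-led$specificity * (led$sensitivity == 100), led$size), ]
  cat(sprintf("\nLedger: %d subsets evaluated; best rows:\n", nrow(led)))
  print(utils::head(led, n_ledger), row.names = FALSE)
  if (!is.null(object$model$cv_table)) {
    cat(sprintf("\nCross-validation (%d folds, seed %d), held-out metrics:\n",
                object$folds_used, object$seed))
    print(object$model$cv_table, row.names = FALSE)
  }
  invisible(object)
}

#' Primary weights of a fitted screening model
#'
#' @param object an `nbs_screen` fit.
#' @param ... unused.
#' @return named numeric vector of signed primary weights per analyte.
#' @export
coef.nbs_screen <- function(object, ...) {
  stats::setNames(object$weights$weight, object$weights$analyte)
}

#' Two-stage prediction with a fitted screening model
#'
#' @param object an `nbs_screen` fit with a winning model.
#' @param newdata an `nbs_cohort`.
#' @param classify_band_only diagnostic-cutoff exceeders bypass the
#'   classifier as positives (default `TRUE`; see [two_stage_predict()]).
#' @param classify_all bypass the stage-1 cutoff gate (default `FALSE`).
#' @param ... unused.
#' @return the [two_stage_predict()] data frame.
#' @export
predict.nbs_screen <- function(object, newdata, classify_band_only = TRUE,
                               classify_all = FALSE, ...) {
  if (is.null(object$model)) {
    stop_nbs("no model was selected (no subset reached 100%% sensitivity)",
             class = "nbs_config_error")
  }
  two_stage_predict(newdata, object$disease, object$model,
                    classify_band_only = classify_band_only,
                    classify_all = classify_all)
}

#' Evaluate a fitted model against the cutoff baseline on a cohort
#'
#' Runs the two-stage prediction and the current cutoff scheme on the same
#' cohort and tabulates both against confirmed truth.
#'
#' @param object an `nbs_screen` fit.
#' @param cohort evaluation `nbs_cohort`.
#' @param truth confirmed labels (default: the cohort's own `confirmed`).
#' @return a [comparison_report()].
#' @export
evaluate_screen <- function(object, cohort, truth = NULL) {
  stopifnot(inherits(object, "nbs_screen"))
  truth <- truth %||% cohort$confirmed
  pred <- predict(object, cohort)
  proposed <- confusion(pred$screen_positive, truth)
  current <- baseline_current_method(triage(cohort, object$disease), truth)
  comparison_report(current, proposed, object$disease)
}

#' Plot the F-score ranking of a fitted screening model
#'
#' Horizontal bars of the top-ranked features' F-scores, with the winning
#' subset's features highlighted.
#'
#' @param x an `nbs_screen` fit.
#' @param n number of features shown (default 15).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted data frame.
#' @export
plot.nbs_screen <- function(x, n = 15, ...) {
  df <- utils::head(as.data.frame(x$ranked), n)
  win <- if (is.null(x$selection$winner)) character(0) else
    feature_displays(x$selection$winner)
  cols <- ifelse(df$feature %in% win, "firebrick", "grey60")
  fs <- df$f_score
  fs[!is.finite(fs)] <- max(fs[is.finite(fs)], 1) * 1.2
  op <- graphics::par(mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(fs), names.arg = rev(df$feature), horiz = TRUE,
                    las = 1, col = rev(cols), xlab = "F-score",
                    main = sprintf("%s: feature ranking", x$disease$name), ...)
  invisible(df)
}
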