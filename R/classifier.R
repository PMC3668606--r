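#' RBF support vector classifier settings
#'
#' @param C slack (cost) parameter, positive; default 100.
#' @param gamma RBF kernel width, positive, or `"auto"` (default) meaning the
#'   reciprocal of the number of input features.
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(C = 100, gamma = "auto") {
  stopifnot(is.numeric(C), C > 0)
  if (!(identical(gamma, "auto") || (is.numeric(gamma) && gamma > 0))) {
    stop_nbs("gamma must be a positive number or \"auto\"", class = "nbs_config_error")
  }
  structure(list(C = as.numeric(C), gamma = gamma), class = "classifier_spec")
}

#' Train an RBF-kernel support vector classifier
#'
#' Fits a maximum-margin classifier (libsvm via \pkg{e1071}) on a feature
#' matrix. Features are standardized using the training mean and standard
#' deviation (zero-variance features get unit scale); the scaler is stored in
#' the model and applied to prediction inputs. `gamma = "auto"` resolves to
#' `1 / ncol(x)`.
#'
#' @param x numeric feature matrix (records by features).
#' @param y class labels: logical, or `positive`/`suspected`, with the
#'   confirmed-disease class as positive. Both classes must be present.
#' @param spec a [classifier_spec()].
#' @param features optional list of [feature_spec()]s describing the columns
#'   of `x` (kept for provenance).
#' @param fingerprint optional list (seed, fold id, ...) recorded in the model.
#' @return an object of class `nbs_model`.
#' @export
train_classifier <- function(x, y, spec = classifier_spec(), features = NULL,
                             fingerprint = list()) {
  x <- as.matrix(x)
  is_pos <- as_positive_indicator(y)
  if (length(unique(is_pos)) < 2L) {
    stop_nbs("training labels contain a single class", class = "nbs_training_error")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- scale(x, center = center, scale = scale_)
  gamma <- if (identical(spec$gamma, "auto")) 1 / ncol(x) else spec$gamma
  y_fac <- factor(ifelse(is_pos, "positive", "suspected"),
                  levels = c("suspected", "positive"))
  fit <- e1071::svm(xs, y_fac, type = "C-classification", kernel = "radial",
                    cost = spec$C, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale_, gamma = gamma,
                 spec = spec, features = features, fingerprint = fingerprint),
            class = "nbs_model")
}

#' @export
print.nbs_model <- function(x, ...) {
  cat(sprintf("<nbs_model> RBF SVM, C = %g, gamma = %g, %d feature(s)\n",
              x$spec$C, x$gamma, length(x$center)))
  if (!is.null(x$features)) {
    cat("  features:", paste(feature_displays(x$features), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Predict with a trained classifier
#'
#' @param object an `nbs_model` from [train_classifier()].
#' @param newdata numeric feature matrix with the same columns as training.
#' @param ... unused.
#' @return factor of predicted labels (`suspected`/`positive`).
#' @export
predict.nbs_model <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), center = object$center, scale = object$scale)
  stats::predict(object$fit, xs)
}

sens_spec <- function(pred_pos, truth_pos) {
  tp <- sum(pred_pos & truth_pos); fn <- sum(!pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fp <- sum(pred_pos & !truth_pos)
  c(sensitivity = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp))
}

#' Train on one split and score a feature subset on another
#'
#' Trains an RBF SVM on the training split restricted to the given feature
#' subset and reports sensitivity and specificity (percent) on the
#' evaluation split, with confirmed positives as the positive class and
#' suspecteds as the negative class.
#'
#' @param subset non-empty list of [feature_spec()]s.
#' @param train_cohort,train_labels training `nbs_cohort` and labels.
#' @param eval_cohort,eval_labels evaluation `nbs_cohort` and labels.
#' @param spec a [classifier_spec()].
#' @param eps ratio denominator guard.
#' @return named numeric `c(sensitivity, specificity)` in `[0, 100]`.
#' @export
evaluate_subset <- function(subset, train_cohort, train_labels,
                            eval_cohort, eval_labels,
                            spec = classifier_spec(), eps = 1e-6) {
  if (length(subset) == 0L) {
    stop_nbs("feature subset must be non-empty", class = "nbs_config_error")
  }
  x_tr <- evaluate_features(train_cohort, subset, eps = eps)
  x_ev <- evaluate_features(eval_cohort, subset, eps = eps)
  model <- train_classifier(x_tr, train_labels, spec, features = subset)
  pred <- predict(model, x_ev) == "positive"
  sens_spec(pred, as_positive_indicator(eval_labels))
}

#' Exhaustive feature-subset search under the 100%-sensitivity criterion
#'
#' Enumerates every non-empty subset of the top `max_rank` ranked features
#' (`2^max_rank - 1` subsets), trains and scores each with
#' [evaluate_subset()], and selects the winner by, in order: (1) sensitivity
#' of exactly 100%, (2) highest specificity, (3) fewest features, (4) highest
#' summed F-score, (5) earliest in canonical enumeration order (subsets
#' ordered by size, then lexicographically by rank indices). If no subset
#' reaches 100% sensitivity the result has a `NULL` winner (no error); the
#' full per-subset ledger is always returned for audit.
#'
#' Enumerating all subsets of 20 features trains about a million classifiers;
#' sizes above 15 therefore require `full_search = TRUE`.
#'
#' @param ranked a [rank_features()] result.
#' @param train_cohort,train_labels training split.
#' @param eval_cohort,eval_labels evaluation split used for the per-subset
#'   sensitivity/specificity.
#' @param spec a [classifier_spec()].
#' @param max_rank number of top-ranked features searched over (default 10).
#' @param full_search set `TRUE` to allow `max_rank > 15`.
#' @param eps ratio denominator guard.
#' @return an object of class `selection_result`: `winner` (feature_spec
#'   list or `NULL`), `winner_index`, `ledger` (data frame: `index`, `size`,
#'   `features`, `sensitivity`, `specificity`, `sum_f`), and `criterion`
#'   (text trace of how the winner was chosen).
#' @export
search_optimal_subset <- function(ranked, train_cohort, train_labels,
                                  eval_cohort, eval_labels,
                                  spec = classifier_spec(), max_rank = 10,
                                  full_search = FALSE, eps = 1e-6) {
  stopifnot(inherits(ranked, "ranked_features"))
  specs <- attr(ranked, "specs")
  K <- min(as.integer(max_rank), length(specs))
  if (K < 1L) stop_nbs("max_rank must be at least 1", class = "nbs_config_error")
  if (K > 15L && !full_search) {
    stop_nbs("max_rank = %d enumerates %.0f subsets; set full_search = TRUE to allow it",
             K, 2^K - 1, class = "nbs_config_error")
  }
  specs <- specs[seq_len(K)]
  fs <- ranked$f_score[seq_len(K)]

  # precompute feature columns once; each subset reuses them
  x_tr <- evaluate_features(train_cohort, specs, eps = eps)
  x_ev <- evaluate_features(eval_cohort, specs, eps = eps)
  truth_ev <- as_positive_indicator(eval_labels)

  subsets <- enumerate_subsets(K)
  n_sub <- length(subsets)
  ledger <- data.frame(index = seq_len(n_sub), size = lengths(subsets),
                       features = NA_character_, sensitivity = NA_real_,
                       specificity = NA_real_, sum_f = NA_real_,
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_sub)) {
    idx <- subsets[[i]]
    model <- train_classifier(x_tr[, idx, drop = FALSE], train_labels, spec,
                              features = specs[idx])
    pred <- predict(model, x_ev[, idx, drop = FALSE]) == "positive"
    ss <- sens_spec(pred, truth_ev)
    ledger$features[i] <- paste(feature_displays(specs[idx]), collapse = "; ")
    ledger$sensitivity[i] <- ss[["sensitivity"]]
    ledger$specificity[i] <- ss[["specificity"]]
    ledger$sum_f[i] <- sum(fs[idx])
  }
  pick <- pick_winner(ledger)
  structure(list(
    winner = if (is.na(pick)) NULL else specs[subsets[[pick]]],
    winner_index = if (is.na(pick)) NA_integer_ else pick,
    ledger = ledger,
    criterion = paste("sensitivity == 100, then max specificity, then fewest",
                      "features, then max summed F-score, then enumeration order"),
    ranked = specs, max_rank = K
  ), class = "selection_result")
}

# all non-empty subsets of 1..k, ordered by size then lexicographically
enumerate_subsets <- function(k) {
  out <- list()
  for (s in seq_len(k)) {
    out <- c(out, utils::combn(k, s, simplify = FALSE))
  }
  out
}

# winner row index by the documented tie-break chain; NA when no subset
# attains 100% sensitivity
pick_winner <- function(ledger) {
  ok <- which(!is.na(ledger$sensitivity) & ledger$sensitivity == 100 &
                !is.na(ledger$specificity))
  if (!length(ok)) return(NA_integer_)
  sub <- ledger[ok, , drop = FALSE]
  ok[order(-sub$specificity, sub$size, -sub$sum_f, sub$index, method = "radix")[1]]
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d subsets over top %d features\n",
              nrow(x$ledger), x$max_rank))
  if (is.null(x$winner)) {
    cat("  no subset reached 100% sensitivity\n")
  } else {
    row <- x$ledger[x$winner_index, ]
    cat(sprintf("  winner: {%s}  sensitivity %.3f%%, specificity %.3f%%\n",
                row$features, row$sensitivity, row$specificity))
  }
  invisible(x)
}

# deterministic stratified split: fraction `frac` of each class held out
stratified_split <- function(is_pos, frac = 0.2, seed = 0) {
  idx <- seq_along(is_pos)
  heldout <- integer(0)
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    members <- idx[is_pos == cls]
    n_hold <- max(1L, round(length(members) * frac))
    n_hold <- min(n_hold, length(members) - 1L)  # keep at least one in train
    heldout <- c(heldout, sort(sample(members, n_hold)))
  }
  list(train = setdiff(idx, heldout), eval = sort(heldout))
}

# deterministic stratified fold assignment
stratified_folds <- function(is_pos, folds, seed) {
  assignment <- integer(length(is_pos))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    members <- which(is_pos == cls)
    assignment[members] <- sample(rep(seq_len(folds), length.out = length(members)))
  }
  assignment
}

#' Pick the optimal model by stratified k-fold cross-validation
#'
#' Assigns records to `folds` stratified folds (seeded, deterministic),
#' trains one model per fold on the remaining folds, scores each on its
#' held-out fold, and returns the model with the highest held-out specificity
#' among those with 100% held-out sensitivity. If no fold model reaches 100%
#' sensitivity, the fallback is highest sensitivity, then specificity, then
#' fold order. The returned model's fingerprint records the seed and winning
#' fold; `cv_table` holds every fold's held-out metrics.
#'
#' @param subset feature subset (list of [feature_spec()]s).
#' @param cohort training `nbs_cohort`.
#' @param labels training labels.
#' @param spec a [classifier_spec()].
#' @param folds number of folds (default 5); each class must have at least
#'   `folds` members.
#' @param seed integer seed for fold assignment (default 0).
#' @param refit if `TRUE`, after the fold comparison the returned model is
#'   refit on all records (the cross-validation table is kept); by default
#'   the winning fold's model itself is returned.
#' @param eps ratio denominator guard.
#' @return an `nbs_model` with an extra `cv_table` element.
#' @export
crossvalidate_optimal_model <- function(subset, cohort, labels,
                                        spec = classifier_spec(), folds = 5,
                                        seed = 0, refit = FALSE, eps = 1e-6) {
  is_pos <- as_positive_indicator(labels)
  folds <- as.integer(folds)
  if (min(sum(is_pos), sum(!is_pos)) < folds) {
    stop_nbs("each class needs at least %d records for %d-fold stratification",
             folds, folds, class = "nbs_config_error")
  }
  x <- evaluate_features(cohort, subset, eps = eps)
  assignment <- stratified_folds(is_pos, folds, seed)
  models <- vector("list", folds)
  cv <- data.frame(fold = seq_len(folds), sensitivity = NA_real_,
                   specificity = NA_real_)
  for (f in seq_len(folds)) {
    tr <- assignment != f
    models[[f]] <- train_classifier(x[tr, , drop = FALSE], is_pos[tr], spec,
                                    features = subset,
                                    fingerprint = list(seed = seed, fold = f))
    pred <- predict(models[[f]], x[!tr, , drop = FALSE]) == "positive"
    ss <- sens_spec(pred, is_pos[!tr])
    cv$sensitivity[f] <- ss[["sensitivity"]]
    cv$specificity[f] <- ss[["specificity"]]
  }
  hit <- which(!is.na(cv$sensitivity) & cv$sensitivity == 100)
  best <- if (length(hit)) {
    hit[order(-cv$specificity[hit], hit, method = "radix")[1]]
  } else {
    order(-cv$sensitivity, -cv$specificity, cv$fold, method = "radix")[1]
  }
  model <- if (refit) {
    train_classifier(x, is_pos, spec, features = subset,
                     fingerprint = list(seed = seed, fold = NA, refit = TRUE))
  } else {
    models[[best]]
  }
  model$cv_table <- cv
  model$fingerprint$selected_fold <- best
  model
}
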