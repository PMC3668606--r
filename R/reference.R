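#' Published NTUH screening benchmark: triage counts 2006-2011
#'
#' Suspected and positive case counts per disease observed over 347,312
#' newborn samples screened at the NTUH Newborn Screening Center between 2006
#' and 2011, together with the cohort size. These published tallies are the
#' inputs for rate-matched synthetic scenarios ([make_scenario()]) and for
#' bookkeeping checks.
#'
#' @return a data frame with columns `disease`, `marker`, `suspected`,
#'   `positive`, plus an attribute `n_total` (347312).
#' @export
reference_screen_counts <- function() {
  structure(
    data.frame(
      disease = c("pku", "hypermethioninemia", "mcc"),
      marker = c("Phe", "Met", "C5OH"),
      suspected = c(203L, 261L, 1093L),
      positive = c(38L, 40L, 142L),
      stringsAsFactors = FALSE
    ),
    n_total = 347312L
  )
}

#' Published NTUH prediction benchmark: 2011 confusion counts
#'
#' Confusion counts per disease from predicting the 2011 samples of the NTUH
#' cohort, for the proposed (two-stage classifier) method and, where
#' published, the current cutoff scheme. The current method's true-negative
#' and false-negative cells were not published (`NA`); under the no-false-
#' negative assumption its TN is recoverable as
#' `(proposed TN + proposed FP) - current FP` (see
#' [derive_current_confusion()]).
#'
#' @return a data frame with columns `disease`, `method`, `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
reference_prediction_counts <- function() {
  data.frame(
    disease = rep(c("pku", "hypermethioninemia", "mcc"), each = 2),
    method = rep(c("current", "proposed"), 3),
    TP = c(3L, 3L, 3L, 3L, 6L, 6L),
    TN = c(NA, 72111L, NA, 72112L, NA, 72255L),
    FP = c(21L, 2L, 30L, 10L, 209L, 46L),
    FN = c(NA, 0L, NA, 0L, NA, 0L),
    stringsAsFactors = FALSE
  )
}

#' Recover the current method's confusion counts from the proposed method's
#'
#' The cutoff scheme's true negatives are not published directly; assuming no
#' false negatives and the same evaluated 2011 samples, the number of
#' evaluated non-diseased records equals `proposed TN + proposed FP`, so the
#' current method's TN is that total minus its own FP, and its FN is 0.
#'
#' @param proposed a [confusion_counts()] for the proposed method.
#' @param current_fp the current method's published false-positive count.
#' @param current_tp the current method's true-positive count (defaults to
#'   the proposed method's, both screens catching every confirmed case).
#' @return a [confusion_counts()] for the current method.
#' @export
derive_current_confusion <- function(proposed, current_fp, current_tp = proposed$TP) {
  stopifnot(inherits(proposed, "confusion_counts"))
  negatives <- proposed$TN + proposed$FP
  confusion_counts(TP = current_tp, TN = negatives - current_fp,
                   FP = current_fp, FN = 0L)
}
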