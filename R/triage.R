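#' Disease definitions for cutoff triage
#'
#' A disease is screened on a single primary marker with two thresholds: a
#' screening cutoff (recall for a repeat dried-blood-spot) and a higher
#' diagnostic cutoff (referral for a confirmation test).
#'
#' @param name disease name.
#' @param marker analyte abbreviation of the primary screening marker.
#' @param screening_cutoff screening cutoff in micromolar.
#' @param diagnostic_cutoff diagnostic cutoff in micromolar; must exceed the
#'   screening cutoff.
#' @return a `disease_definition` object.
#' @examples
#' disease_definition("PKU", "Phe", 85.02, 220)
#' @export
disease_definition <- function(name, marker, screening_cutoff, diagnostic_cutoff) {
  stopifnot(is.character(name), is.character(marker),
            is.numeric(screening_cutoff), is.numeric(diagnostic_cutoff))
  if (!(screening_cutoff < diagnostic_cutoff)) {
    stop_nbs("screening cutoff (%g) must be below the diagnostic cutoff (%g)",
             screening_cutoff, diagnostic_cutoff, class = "nbs_config_error")
  }
  structure(list(name = name, marker = marker,
                 screening_cutoff = as.numeric(screening_cutoff),
                 diagnostic_cutoff = as.numeric(diagnostic_cutoff)),
            class = "disease_definition")
}

#' @export
print.disease_definition <- function(x, ...) {
  cat(sprintf("<disease_definition> %s: %s > %g uM (screening), > %g uM (diagnostic)\n",
              x$name, x$marker, x$screening_cutoff, x$diagnostic_cutoff))
  invisible(x)
}

#' Built-in disease definitions
#'
#' The three conditions screened by the NTUH newborn screening centre panel
#' that this package targets, with their published cutoffs: phenylketonuria
#' (Phe), hypermethioninemia (Met) and 3-MCC deficiency (C5OH).
#'
#' @return named list of [disease_definition()] objects with names `"pku"`,
#'   `"hypermethioninemia"`, `"mcc"`.
#' @export
default_diseases <- function() {
  list(
    pku = disease_definition("PKU", "Phe", 85.02, 220),
    hypermethioninemia = disease_definition("Hypermethioninemia", "Met", 54.12, 110),
    mcc = disease_definition("3-MCC deficiency", "C5OH", 0.56, 2.2)
  )
}

TRIAGE_LEVELS <- c("negative", "suspected", "positive")

#' Cutoff triage of marker values
#'
#' Classifies each record for one disease from its primary-marker
#' concentration: `positive` strictly above the diagnostic cutoff,
#' `suspected` in the closed interval from the screening cutoff to the
#' diagnostic cutoff, `negative` strictly below the screening cutoff.
#' Boundary semantics: a value exactly equal to either cutoff is `suspected`
#' (the screening band is closed on both ends); this convention is recorded
#' in the result's `boundary` attribute since cutoff tables are often printed
#' with a bare `>`.
#'
#' @param x a named numeric vector of analyte concentrations (one record), an
#'   unnamed numeric vector of marker values, or an `nbs_cohort`.
#' @param disease a [disease_definition()].
#' @return a factor with levels `negative`, `suspected`, `positive`, one
#'   element per record.
#' @examples
#' pku <- default_diseases()$pku
#' triage(c(Phe = 230), pku)  # positive
#' triage(c(Phe = 100), pku)  # suspected
#' triage(c(Phe = 50), pku)   # negative
#' @export
triage <- function(x, disease) {
  stopifnot(inherits(disease, "disease_definition"))
  v <- marker_values(x, disease)
  lab <- ifelse(v > disease$diagnostic_cutoff, "positive",
                ifelse(v >= disease$screening_cutoff, "suspected", "negative"))
  structure(factor(lab, levels = TRIAGE_LEVELS),
            boundary = "suspected = [screening, diagnostic]; positive = (diagnostic, Inf)")
}

marker_values <- function(x, disease) {
  if (inherits(x, "nbs_cohort")) {
    if (!disease$marker %in% as.character(x$panel)) {
      stop_nbs("marker %s for %s is not in the cohort panel",
               disease$marker, disease$name, class = "nbs_config_error")
    }
    x$values[, disease$marker]
  } else if (is.numeric(x)) {
    if (!is.null(names(x))) {
      if (!disease$marker %in% names(x)) {
        stop_nbs("marker %s for %s is not among the named values",
                 disease$marker, disease$name, class = "nbs_config_error")
      }
      unname(x[disease$marker])
    } else x
  } else {
    stop_nbs("x must be a numeric vector or an nbs_cohort", class = "nbs_format_error")
  }
}

#' Triage a whole cohort for one disease
#'
#' @param cohort an `nbs_cohort`.
#' @param disease a [disease_definition()].
#' @return a list of class `triage_result` with elements `labels` (factor per
#'   record, as [triage()]), `counts` (named integer vector over
#'   negative/suspected/positive, summing to the cohort size) and `disease`.
#' @export
triage_cohort <- function(cohort, disease) {
  stopifnot(inherits(cohort, "nbs_cohort"))
  labels <- triage(cohort, disease)
  counts <- table(labels)
  structure(list(labels = labels,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 disease = disease),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %s: %d negative, %d suspected, %d positive\n",
              x$disease$name, x$counts[["negative"]], x$counts[["suspected"]],
              x$counts[["positive"]]))
  invisible(x)
}
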