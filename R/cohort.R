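CONFIRMED_LEVELS <- c("diseased", "not_diseased", "unknown")

#' Screening cohorts
#'
#' A cohort bundles an analyte panel with an ordered collection of screening
#' records: one sample per newborn, each carrying an opaque sample id, a
#' calendar year, a concentration (micromolar) for every panel analyte, and an
#' optional confirmed-disease label.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param year integer calendar year per record.
#' @param values numeric matrix, one row per record and one column per panel
#'   analyte (column order must match the panel); all concentrations must be
#'   finite and non-negative.
#' @param confirmed confirmed-disease label per record: `"diseased"`,
#'   `"not_diseased"` or `"unknown"`. Defaults to `"unknown"`.
#' @param panel an [analyte_panel()]; defaults to [default_panel()].
#' @return an object of class `nbs_cohort`.
#' @examples
#' p <- analyte_panel(c("Phe", "Met"))
#' new_cohort(c("s1", "s2"), c(2010L, 2011L),
#'            matrix(c(50, 60, 20, 25), 2, 2), panel = p)
#' @export
new_cohort <- function(sample_id, year, values, confirmed = NULL,
                       panel = default_panel()) {
  panel <- as_panel(panel)
  values <- as.matrix(values)
  n <- length(sample_id)
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop_nbs("duplicate sample_id(s): %s",
             paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
             class = "nbs_format_error")
  }
  year <- as.integer(year)
  if (length(year) != n || nrow(values) != n) {
    stop_nbs("sample_id, year and values must describe the same records",
             class = "nbs_format_error")
  }
  if (ncol(values) != length(panel)) {
    stop_nbs("values has %d columns but the panel has %d analytes",
             ncol(values), length(panel), class = "nbs_format_error")
  }
  if (n > 0 && (anyNA(values) || any(!is.finite(values)) || any(values < 0))) {
    bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop_nbs("invalid concentration at record %d, analyte %s (must be a finite non-negative number)",
             bad[["row"]], panel[bad[["col"]]], class = "nbs_value_error")
  }
  confirmed <- as.character(confirmed %||% rep("unknown", n))
  if (length(confirmed) != n || !all(confirmed %in% CONFIRMED_LEVELS)) {
    stop_nbs("confirmed labels must each be one of: %s",
             paste(CONFIRMED_LEVELS, collapse = ", "), class = "nbs_value_error")
  }
  colnames(values) <- as.character(panel)
  rownames(values) <- NULL
  structure(
    list(panel = panel, sample_id = sample_id, year = year,
         confirmed = confirmed, values = values),
    class = "nbs_cohort"
  )
}

#' Number of records in a cohort
#' @param cohort an `nbs_cohort`.
#' @return integer record count.
#' @export
n_records <- function(cohort) length(cohort$sample_id)

#' @export
print.nbs_cohort <- function(x, ...) {
  yrs <- if (n_records(x)) paste(range(x$year), collapse = "-") else "none"
  cat(sprintf("<nbs_cohort> %d records, %d analytes, years %s\n",
              n_records(x), length(x$panel), yrs))
  tab <- table(factor(x$confirmed, levels = CONFIRMED_LEVELS))
  cat(sprintf("  confirmed: %d diseased / %d not_diseased / %d unknown\n",
              tab[["diseased"]], tab[["not_diseased"]], tab[["unknown"]]))
  invisible(x)
}

#' @export
`[.nbs_cohort` <- function(x, i, ...) {
  new_cohort(x$sample_id[i], x$year[i], x$values[i, , drop = FALSE],
             x$confirmed[i], x$panel)
}

#' @export
as.data.frame.nbs_cohort <- function(x, ...) {
  data.frame(sample_id = x$sample_id, year = x$year, confirmed = x$confirmed,
             as.data.frame(x$values, check.names = FALSE),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a screening cohort from CSV
#'
#' The file must be comma-separated UTF-8 with a header row naming
#' `sample_id`, `year`, optionally `confirmed`, and one column per panel
#' analyte (names matched exactly, case-sensitively, to avoid silent column
#' misbinding). Missing `confirmed` values become `"unknown"`.
#'
#' @param path path to a CSV file.
#' @param panel an [analyte_panel()], or `NULL` to infer the panel from the
#'   non-metadata columns in file order.
#' @return an `nbs_cohort` whose record order matches the file.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, panel = default_panel()) {
  if (!file.exists(path)) {
    stop_nbs("cohort file does not exist: %s", path, class = "nbs_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  meta <- c("sample_id", "year", "confirmed")
  if (anyDuplicated(names(df))) {
    stop_nbs("duplicate column(s) in %s: %s", path,
             paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
             class = "nbs_format_error")
  }
  if (!all(c("sample_id", "year") %in% names(df))) {
    stop_nbs("cohort file must have sample_id and year columns", class = "nbs_format_error")
  }
  if (is.null(panel)) {
    panel <- analyte_panel(setdiff(names(df), meta))
  } else {
    panel <- as_panel(panel)
    missing <- setdiff(as.character(panel), names(df))
    if (length(missing)) {
      stop_nbs("cohort file lacks analyte column(s): %s",
               paste(missing, collapse = ", "), class = "nbs_format_error")
    }
  }
  vals <- matrix(NA_real_, nrow(df), length(panel),
                 dimnames = list(NULL, as.character(panel)))
  for (a in as.character(panel)) {
    v <- suppressWarnings(as.numeric(df[[a]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop_nbs("invalid concentration '%s' at row %d, column %s",
               df[[a]][bad[1]], bad[1], a, class = "nbs_value_error")
    }
    vals[, a] <- v
  }
  year <- suppressWarnings(as.integer(df$year))
  if (nrow(df) > 0 && anyNA(year)) {
    stop_nbs("non-integer year at row %d", which(is.na(year))[1], class = "nbs_value_error")
  }
  confirmed <- if ("confirmed" %in% names(df)) {
    cf <- df$confirmed
    cf[is.na(cf) | cf == ""] <- "unknown"
    cf
  } else NULL
  new_cohort(df$sample_id, year, vals, confirmed, panel)
}

#' Write a screening cohort to CSV
#'
#' Emits one header row then one row per record, analyte columns in panel
#' order. Concentrations are written with 17 significant digits so
#' `read_cohort(write_cohort(c))` reproduces every value exactly.
#'
#' @param cohort an `nbs_cohort`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nbs_cohort"))
  df <- data.frame(sample_id = cohort$sample_id, year = cohort$year,
                   confirmed = cohort$confirmed,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (a in as.character(cohort$panel)) {
    df[[a]] <- sprintf("%.17g", cohort$values[, a])
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_nbs("cannot write cohort to %s: %s", path, conditionMessage(ok),
             class = "nbs_io_error")
  }
  invisible(path)
}

#' Subset a cohort by calendar year
#'
#' @param cohort an `nbs_cohort`.
#' @param years integer vector of years to keep; records whose year is in
#'   `years` are returned in their original order. An empty selection yields
#'   an empty cohort.
#' @return an `nbs_cohort`.
#' @export
subset_by_year <- function(cohort, years) {
  stopifnot(inherits(cohort, "nbs_cohort"))
  cohort[cohort$year %in% as.integer(years)]
}
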