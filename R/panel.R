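#' Analyte panels
#'
#' An analyte panel is an ordered set of unique analyte abbreviations (amino
#' acids and acylcarnitines) measured by MS/MS from one dried blood spot, all
#' expressed in micromolar concentration.
#'
#' @param names character vector of analyte abbreviations (e.g. `"Phe"`,
#'   `"C5OH"`). Must be unique and non-empty.
#' @param units concentration unit tag; only `"uM"` is supported.
#' @return an `analyte_panel` object (a character vector with a units
#'   attribute).
#' @examples
#' analyte_panel(c("Phe", "Met", "C5OH"))
#' @export
analyte_panel <- function(names, units = "uM") {
  if (!is.character(names) || length(names) == 0L) {
    stop_nbs("an analyte panel needs at least one analyte name", class = "nbs_format_error")
  }
  if (any(!nzchar(names)) || anyNA(names)) {
    stop_nbs("analyte names must be non-empty strings", class = "nbs_format_error")
  }
  if (anyDuplicated(names)) {
    stop_nbs("duplicate analyte name(s): %s",
             paste(unique(names[duplicated(names)]), collapse = ", "),
             class = "nbs_format_error")
  }
  units <- match.arg(units)
  structure(as.character(names), units = units, class = "analyte_panel")
}

#' Default 35-analyte MS/MS screening panel
#'
#' Ten amino acids and twenty-five acylcarnitines, covering all markers used
#' by the triage definitions in [default_diseases()] together with the
#' standard species reported by MS/MS newborn screening. User-overridable
#' everywhere a panel is accepted.
#'
#' @return an [analyte_panel()] of length 35.
#' @export
default_panel <- function() {
  analyte_panel(c(
    # amino acids
    "Ala", "Arg", "Cit", "Gly", "Leu", "Met", "Orn", "Phe", "Tyr", "Val",
    # acylcarnitines
    "C0", "C2", "C3", "C4", "C5", "C5:1", "C5OH", "C5DC",
    "C6", "C6DC", "C8", "C8:1", "C10", "C10:1", "C10:2",
    "C12", "C12:1", "C14", "C14:1", "C14:2",
    "C16", "C16:1", "C18", "C18:1", "C18:2"
  ))
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat(sprintf("<analyte_panel> %d analytes (%s)\n", length(x), attr(x, "units")))
  cat(" ", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

as_panel <- function(panel) {
  if (inherits(panel, "analyte_panel")) panel else analyte_panel(panel)
}
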