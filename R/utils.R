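`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' reported percentages), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# locale-independent sort (C collation) so orderings are reproducible
canonical_sort <- function(x) sort(x, method = "radix")

canonical_order <- function(...) order(..., method = "radix")

stop_nbs <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "nbs_error")))
}
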