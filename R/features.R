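TIMES <- "\u00d7"  # multiplication sign used in feature display strings

#' Feature specifications
#'
#' A feature is either a raw analyte, the product of two distinct analytes,
#' or the ratio of two distinct analytes. Product operands are stored in
#' canonical (C-collation sorted) order so that `A×B` and `B×A` are the same
#' feature; ratios are directional.
#'
#' @param kind one of `"raw"`, `"product"`, `"ratio"`.
#' @param operands character vector of 1 (raw) or 2 (product/ratio) analyte
#'   names; for a ratio, numerator first.
#' @return a `feature_spec` object with a `display` field such as `"Phe"`,
#'   `"Leu×Tyr"` or `"Orn/C16"`.
#' @examples
#' feature_spec("product", c("Tyr", "Leu"))$display  # "Leu×Tyr"
#' @export
feature_spec <- function(kind = c("raw", "product", "ratio"), operands) {
  kind <- match.arg(kind)
  operands <- as.character(operands)
  n_needed <- if (kind == "raw") 1L else 2L
  if (length(operands) != n_needed) {
    stop_nbs("%s features take %d operand(s)", kind, n_needed, class = "nbs_format_error")
  }
  if (n_needed == 2L && operands[1] == operands[2]) {
    stop_nbs("%s operands must be distinct analytes", kind, class = "nbs_format_error")
  }
  if (kind == "product") operands <- canonical_sort(operands)
  display <- switch(kind,
    raw = operands,
    product = paste0(operands[1], TIMES, operands[2]),
    ratio = paste0(operands[1], "/", operands[2]))
  structure(list(kind = kind, operands = operands, display = display),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s (%s)\n", x$display, x$kind))
  invisible(x)
}

#' @export
format.feature_spec <- function(x, ...) x$display

#' Parse a feature display string
#'
#' Inverse of the `display` field: `"Phe"` is raw, `"Leu×Tyr"` (or
#' `"Leu*Tyr"`) a product, `"Orn/C16"` a ratio.
#'
#' @param x character vector of feature strings.
#' @return a list of [feature_spec()] objects.
#' @export
parse_features <- function(x) {
  lapply(as.character(x), function(s) {
    if (grepl(TIMES, s, fixed = TRUE) || grepl("*", s, fixed = TRUE)) {
      sep <- if (grepl(TIMES, s, fixed = TRUE)) TIMES else "*"
      feature_spec("product", strsplit(s, sep, fixed = TRUE)[[1]])
    } else if (grepl("/", s, fixed = TRUE)) {
      feature_spec("ratio", strsplit(s, "/", fixed = TRUE)[[1]])
    } else {
      feature_spec("raw", s)
    }
  })
}

feature_displays <- function(specs) vapply(specs, `[[`, character(1), "display")

# canonical feature ordering for deterministic tie-breaks:
# raw before product before ratio, then C-collation on display
feature_rank <- function(specs) {
  kind <- vapply(specs, `[[`, character(1), "kind")
  canonical_order(match(kind, c("raw", "product", "ratio")), feature_displays(specs))
}

dedupe_features <- function(specs) {
  specs[!duplicated(feature_displays(specs))]
}

#' Primary weights from class median differences
#'
#' For each panel analyte, `D` is the difference of the class medians
#' (confirmed positives minus suspected cases, in micromolar). The signed
#' primary weight is `D` normalized by a robust pooled scale: the
#' interquartile range of the analyte over the pooled positive and suspected
#' records, falling back to the pooled standard deviation when the IQR is
#' zero, then to 1 when both vanish (so the weight's sign always equals the
#' sign of `D`).
#'
#' @param positives `nbs_cohort` of confirmed positive cases (non-empty).
#' @param suspecteds `nbs_cohort` of suspected cases (non-empty, same panel).
#' @return a data frame of class `primary_weights` with one row per analyte:
#'   `analyte`, `D`, `scale`, `scale_type` (`"iqr"`, `"sd"` or `"unit"`),
#'   `weight`.
#' @export
compute_primary_weights <- function(positives, suspecteds) {
  stopifnot(inherits(positives, "nbs_cohort"), inherits(suspecteds, "nbs_cohort"))
  if (n_records(positives) == 0L || n_records(suspecteds) == 0L) {
    stop_nbs("both classes must be non-empty to compute primary weights",
             class = "nbs_insufficient_data")
  }
  if (!identical(as.character(positives$panel), as.character(suspecteds$panel))) {
    stop_nbs("positive and suspected cohorts must share a panel",
             class = "nbs_config_error")
  }
  analytes <- as.character(positives$panel)
  D <- scale_ <- numeric(length(analytes))
  scale_type <- character(length(analytes))
  for (i in seq_along(analytes)) {
    p <- positives$values[, i]
    s <- suspecteds$values[, i]
    D[i] <- stats::median(p) - stats::median(s)
    pooled <- c(p, s)
    sc <- stats::IQR(pooled)
    ty <- "iqr"
    if (sc == 0) {
      sc <- stats::sd(pooled)
      ty <- "sd"
      if (is.na(sc) || sc == 0) {
        sc <- 1
        ty <- "unit"
      }
    }
    scale_[i] <- sc
    scale_type[i] <- ty
  }
  structure(
    data.frame(analyte = analytes, D = D, scale = scale_,
               scale_type = scale_type, weight = D / scale_,
               stringsAsFactors = FALSE),
    class = c("primary_weights", "data.frame")
  )
}

#' Top signed primary-weight markers
#'
#' Returns up to `k` analytes with the largest positive weights and up to `k`
#' with the most negative weights; fewer are returned when fewer analytes
#' have weights of that sign (zero-weight analytes are never selected).
#'
#' @param weights a [compute_primary_weights()] table.
#' @param k maximum markers per sign (default 3).
#' @return list with character vectors `positive` and `negative`, each in
#'   decreasing order of absolute weight.
#' @export
select_signed_top <- function(weights, k = 3) {
  stopifnot(inherits(weights, "primary_weights"), k >= 0)
  pos <- weights[weights$weight > 0, , drop = FALSE]
  neg <- weights[weights$weight < 0, , drop = FALSE]
  pos <- pos[canonical_order(-pos$weight, pos$analyte), , drop = FALSE]
  neg <- neg[canonical_order(neg$weight, neg$analyte), , drop = FALSE]
  list(positive = utils::head(pos$analyte, k),
       negative = utils::head(neg$analyte, k))
}

#' Manifested features from top-weighted markers
#'
#' Enumerates derived features over the selected markers: every unordered
#' pairwise product over the union of positive- and negative-weight markers,
#' plus every ratio positive/negative. For disjoint marker sets of sizes `p`
#' and `n` this yields `choose(p + n, 2) + p * n` features, deduplicated and
#' returned in canonical order.
#'
#' @param pos character vector of positive-weight markers.
#' @param neg character vector of negative-weight markers (disjoint from
#'   `pos`).
#' @return list of [feature_spec()] objects (possibly empty).
#' @export
build_manifested_features <- function(pos, neg) {
  pos <- as.character(pos); neg <- as.character(neg)
  if (length(intersect(pos, neg))) {
    stop_nbs("positive and negative marker lists must be disjoint",
             class = "nbs_config_error")
  }
  all_m <- c(pos, neg)
  specs <- list()
  if (length(all_m) >= 2) {
    prs <- utils::combn(all_m, 2, simplify = FALSE)
    specs <- c(specs, lapply(prs, function(p) feature_spec("product", p)))
  }
  for (p in pos) for (n in neg) {
    specs <- c(specs, list(feature_spec("ratio", c(p, n))))
  }
  specs <- dedupe_features(specs)
  specs[feature_rank(specs)]
}

#' Evaluate features on records
#'
#' Computes the value of each feature for each record: raw features return
#' the concentration, products the product of two concentrations, ratios the
#' quotient with an epsilon-guarded denominator (denominators below `eps` are
#' replaced by `eps`; the number of guarded evaluations is attached as the
#' `"n_guarded"` attribute so downstream QC can count them).
#'
#' @param cohort an `nbs_cohort` (or a numeric matrix with analyte columns).
#' @param specs list of [feature_spec()] objects.
#' @param eps denominator guard in micromolar (default `1e-6`).
#' @return numeric matrix, one row per record and one column per feature
#'   (named by feature display string), with attribute `n_guarded`.
#' @export
evaluate_features <- function(cohort, specs, eps = 1e-6) {
  vals <- if (inherits(cohort, "nbs_cohort")) cohort$values else as.matrix(cohort)
  needed <- unique(unlist(lapply(specs, `[[`, "operands")))
  missing <- setdiff(needed, colnames(vals))
  if (length(missing)) {
    stop_nbs("feature operand(s) not in panel: %s", paste(missing, collapse = ", "),
             class = "nbs_config_error")
  }
  out <- matrix(NA_real_, nrow(vals), length(specs),
                dimnames = list(NULL, feature_displays(specs)))
  guarded <- 0L
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    out[, j] <- switch(sp$kind,
      raw = vals[, sp$operands[1]],
      product = vals[, sp$operands[1]] * vals[, sp$operands[2]],
      ratio = {
        den <- vals[, sp$operands[2]]
        low <- den < eps
        guarded <- guarded + sum(low)
        den[low] <- eps
        vals[, sp$operands[1]] / den
      })
  }
  attr(out, "n_guarded") <- guarded
  out
}

#' Evaluate one feature on one record
#'
#' @param record named numeric vector of analyte concentrations, or a
#'   single-record `nbs_cohort`.
#' @param spec a [feature_spec()].
#' @param eps denominator guard (see [evaluate_features()]).
#' @return scalar feature value, with attribute `guarded` (logical).
#' @export
evaluate_feature <- function(record, spec, eps = 1e-6) {
  m <- if (inherits(record, "nbs_cohort")) record else
    matrix(record, 1, dimnames = list(NULL, names(record)))
  v <- evaluate_features(m, list(spec), eps = eps)
  structure(v[1, 1], guarded = attr(v, "n_guarded") > 0L)
}

#' Two-class F-score of a feature
#'
#' The feature-selection F-score: with class means `m+`, `m-`, overall mean
#' `m`, and class sample variances `s+^2`, `s-^2` (n-1 denominators),
#' \deqn{F = \frac{(m^+ - m)^2 + (m^- - m)^2}{s_+^2 + s_-^2}.}
#' When both class variances are zero the score is 0 if the class means
#' agree and `Inf` otherwise (a perfectly separating constant feature, ranked
#' first).
#'
#' @param pos numeric values of the feature in the positive class (length >= 2).
#' @param neg numeric values in the negative class (length >= 2).
#' @return non-negative scalar (possibly `Inf`).
#' @examples
#' f_score(c(4, 6), c(0, 2))  # 2
#' @export
f_score <- function(pos, neg) {
  if (length(pos) < 2L || length(neg) < 2L) {
    stop_nbs("each class needs at least 2 values for an F-score",
             class = "nbs_insufficient_data")
  }
  m_pos <- mean(pos); m_neg <- mean(neg); m_all <- mean(c(pos, neg))
  num <- (m_pos - m_all)^2 + (m_neg - m_all)^2
  den <- stats::var(pos) + stats::var(neg)
  if (den == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / den
  }
}

#' Rank candidate features by F-score
#'
#' Evaluates every candidate feature on every record, computes the two-class
#' F-score against the labels, and returns the top-ranked features in
#' non-increasing F-score order. Ties are broken by the canonical feature
#' order (raw before product before ratio, then lexicographic), so rankings
#' are fully reproducible.
#'
#' @param cohort training `nbs_cohort` (positives plus suspecteds).
#' @param labels logical or factor; `TRUE`/`"positive"` marks the confirmed
#'   positive class. Each class needs at least 2 records.
#' @param candidates list of [feature_spec()] objects (no duplicates kept).
#' @param top number of features to return (default 20).
#' @param eps ratio denominator guard.
#' @return a data frame of class `ranked_features` with columns `feature`
#'   (display string) and `f_score`, non-increasing, plus attribute `specs`
#'   (the ordered [feature_spec()] list).
#' @export
rank_features <- function(cohort, labels, candidates, top = 20, eps = 1e-6) {
  is_pos <- as_positive_indicator(labels)
  if (sum(is_pos) < 2L || sum(!is_pos) < 2L) {
    stop_nbs("each class needs at least 2 records to rank features",
             class = "nbs_insufficient_data")
  }
  candidates <- dedupe_features(candidates)
  vals <- evaluate_features(cohort, candidates, eps = eps)
  fs <- vapply(seq_along(candidates), function(j) {
    f_score(vals[is_pos, j], vals[!is_pos, j])
  }, numeric(1))
  ord <- order(-fs, rank_key(candidates), method = "radix")
  keep <- utils::head(ord, max(0L, as.integer(top)))
  structure(
    data.frame(feature = feature_displays(candidates)[keep],
               f_score = fs[keep], stringsAsFactors = FALSE),
    specs = candidates[keep],
    class = c("ranked_features", "data.frame")
  )
}

# integer key giving each spec its canonical position among the candidates
rank_key <- function(specs) {
  ord <- feature_rank(specs)
  key <- integer(length(specs))
  key[ord] <- seq_along(specs)
  key
}

as_positive_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (all(l %in% c("positive", "suspected"))) return(l == "positive")
  if (all(l %in% c("diseased", "not_diseased"))) return(l == "diseased")
  stop_nbs("labels must be logical, positive/suspected, or diseased/not_diseased",
           class = "nbs_format_error")
}
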