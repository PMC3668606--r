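#' Baseline concentration distributions for the default panel
#'
#' Log-normal location/scale per analyte for healthy newborns, parameterized
#' by the median concentration (micromolar) and the log-scale standard
#' deviation. The medians are plausible dried-blood-spot values for 3-day-old
#' newborns; the screening markers (Phe, Met, C5OH) get tighter log-scales so
#' that the healthy tail essentially never crosses the screening cutoffs and
#' the suspected band can be modelled explicitly. These are synthetic
#' defaults, not estimates from any real cohort, and are plain config.
#'
#' @param panel an [analyte_panel()].
#' @return data frame with columns `analyte`, `meanlog`, `sdlog`.
#' @export
default_baseline <- function(panel = default_panel()) {
  medians <- c(
    Ala = 250, Arg = 10, Cit = 12, Gly = 350, Leu = 130, Met = 22,
    Orn = 70, Phe = 45, Tyr = 70, Val = 120,
    C0 = 25, C2 = 20, C3 = 2, C4 = 0.3, C5 = 0.15, `C5:1` = 0.03,
    C5OH = 0.2, C5DC = 0.08, C6 = 0.06, C6DC = 0.05, C8 = 0.08,
    `C8:1` = 0.08, C10 = 0.1, `C10:1` = 0.08, `C10:2` = 0.03,
    C12 = 0.1, `C12:1` = 0.05, C14 = 0.2, `C14:1` = 0.08, `C14:2` = 0.03,
    C16 = 3, `C16:1` = 0.2, C18 = 1, `C18:1` = 1.2, `C18:2` = 0.3
  )
  sdlogs <- c(Phe = 0.15, Met = 0.18, C5OH = 0.2)
  panel <- as.character(as_panel(panel))
  med <- ifelse(panel %in% names(medians), medians[panel], 1)
  data.frame(analyte = panel,
             meanlog = log(unname(med)),
             sdlog = unname(ifelse(panel %in% names(sdlogs), sdlogs[panel], 0.25)),
             stringsAsFactors = FALSE)
}

#' Disease scenario for the synthetic generator
#'
#' @param definition a [disease_definition()].
#' @param prevalence fraction of records that are true cases of this disease.
#' @param effect named numeric vector of multiplicative shifts (> 0) applied
#'   to the analytes of a case, e.g. `c(Phe = 10)`.
#' @param suspected_band_rate fraction of records that are healthy
#'   "suspected band" contaminants: their marker is drawn log-uniformly
#'   inside `[screening_cutoff, diagnostic_cutoff)` (so cutoff triage flags
#'   them), but their confirmed label stays `not_diseased`.
#' @return a `disease_scenario` object.
#' @export
disease_scenario <- function(definition, prevalence, effect,
                             suspected_band_rate = 0) {
  stopifnot(inherits(definition, "disease_definition"),
            prevalence >= 0, prevalence <= 1,
            suspected_band_rate >= 0, suspected_band_rate <= 1)
  effect <- unlist(effect)
  if (is.null(names(effect)) || any(!nzchar(names(effect))) || any(effect <= 0)) {
    stop_nbs("effect must be a named vector of positive multipliers",
             class = "nbs_config_error")
  }
  structure(list(definition = definition, prevalence = prevalence,
                 effect = effect, suspected_band_rate = suspected_band_rate),
            class = "disease_scenario")
}

#' Synthetic cohort configuration
#'
#' @param n number of records.
#' @param panel an [analyte_panel()].
#' @param baseline per-analyte log-normal parameters, as [default_baseline()].
#' @param diseases list of [disease_scenario()]s; prevalences plus band rates
#'   must jointly stay below 1.
#' @param correlation optional correlation matrix (panel-sized) for the
#'   analytes' shared log-scale Gaussian; `NULL` (default) for independence.
#' @param seed integer seed making the cohort fully deterministic.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n, panel = default_panel(),
                             baseline = default_baseline(panel),
                             diseases = list(), correlation = NULL, seed = 0) {
  panel <- as_panel(panel)
  stopifnot(n >= 0, is.data.frame(baseline),
            all(c("analyte", "meanlog", "sdlog") %in% names(baseline)))
  if (!setequal(baseline$analyte, as.character(panel))) {
    stop_nbs("baseline must cover exactly the panel analytes", class = "nbs_config_error")
  }
  if (any(!is.finite(baseline$meanlog)) || any(baseline$sdlog <= 0)) {
    stop_nbs("baseline needs finite meanlog and positive sdlog", class = "nbs_config_error")
  }
  for (d in diseases) {
    stopifnot(inherits(d, "disease_scenario"))
    if (!d$definition$marker %in% as.character(panel)) {
      stop_nbs("marker %s is not in the panel", d$definition$marker,
               class = "nbs_config_error")
    }
    missing <- setdiff(names(d$effect), as.character(panel))
    if (length(missing)) {
      stop_nbs("effect analyte(s) not in panel: %s", paste(missing, collapse = ", "),
               class = "nbs_config_error")
    }
  }
  mass <- sum(vapply(diseases, function(d) d$prevalence + d$suspected_band_rate,
                     numeric(1)))
  if (mass >= 1) {
    stop_nbs("prevalences plus suspected-band rates must sum below 1 (got %g)",
             mass, class = "nbs_config_error")
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!all(dim(correlation) == length(panel))) {
      stop_nbs("correlation must be a %d x %d matrix", length(panel), length(panel),
               class = "nbs_config_error")
    }
  }
  structure(list(n = as.integer(n), panel = panel,
                 baseline = baseline[match(as.character(panel), baseline$analyte), ],
                 diseases = diseases, correlation = correlation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a screening cohort
#'
#' Each record is assigned a generative status by one categorical draw:
#' a confirmed case of one disease (probability = that disease's
#' prevalence), a healthy suspected-band contaminant for one disease
#' (probability = that band rate), or plain healthy. All analytes are drawn
#' from the baseline log-normals (optionally correlated on the log scale);
#' cases then multiply their effect analytes, and band records have their
#' disease's marker redrawn log-uniformly inside the screening band.
#' Confirmed labels come from the generative branch, never from cutoffs, so
#' the error rates of any cutoff scheme remain measurable. Identical seed
#' and config give a byte-identical cohort.
#'
#' @param config a [synthetic_config()].
#' @param year calendar year stamped on the records (default 2010).
#' @param seed optional override of `config$seed`.
#' @return a `synthetic_cohort`: list with `cohort` (an `nbs_cohort`),
#'   `status` (per-record string: `"healthy"`, `"case:<disease>"` or
#'   `"band:<disease>"`) and `config`.
#' @export
simulate_cohort <- function(config, year = 2010, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- as.integer(seed %||% config$seed)
  n <- config$n
  p <- length(config$panel)
  set.seed(seed)

  k <- length(config$diseases)
  dname <- vapply(config$diseases, function(d) d$definition$name, character(1))
  probs <- c(vapply(config$diseases, `[[`, numeric(1), "prevalence"),
             vapply(config$diseases, `[[`, numeric(1), "suspected_band_rate"))
  statuses <- c(if (k) paste0("case:", dname), if (k) paste0("band:", dname),
                "healthy")
  probs <- c(probs, 1 - sum(probs))
  status <- if (n) sample(statuses, n, replace = TRUE, prob = probs) else character(0)

  z <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(config$correlation)) {
    z <- z %*% chol(config$correlation)
  }
  vals <- exp(sweep(sweep(z, 2, config$baseline$sdlog, `*`),
                    2, config$baseline$meanlog, `+`))
  colnames(vals) <- as.character(config$panel)

  for (i in seq_len(k)) {
    d <- config$diseases[[i]]
    rows <- which(status == paste0("case:", dname[i]))
    for (a in names(d$effect)) {
      vals[rows, a] <- vals[rows, a] * d$effect[[a]]
    }
    band_rows <- which(status == paste0("band:", dname[i]))
    if (length(band_rows)) {
      lo <- log(d$definition$screening_cutoff)
      hi <- log(d$definition$diagnostic_cutoff)
      vals[band_rows, d$definition$marker] <- exp(stats::runif(length(band_rows), lo, hi))
    }
  }
  confirmed <- ifelse(startsWith(status, "case:"), "diseased", "not_diseased")
  cohort <- new_cohort(sprintf("S%d-%06d", year, seq_len(n)),
                       rep(as.integer(year), n), vals, confirmed, config$panel)
  structure(list(cohort = cohort, status = status, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> seed %d; %d cases, %d band, %d healthy\n",
              x$seed, sum(startsWith(x$status, "case:")),
              sum(startsWith(x$status, "band:")), sum(x$status == "healthy")))
  print(x$cohort)
  invisible(x)
}

#' Disease-specific truth labels for a synthetic cohort
#'
#' @param sim a `synthetic_cohort`.
#' @param disease a [disease_definition()] (matched by name).
#' @return character vector `diseased` / `not_diseased`: diseased only for
#'   cases of this disease.
#' @export
disease_truth <- function(sim, disease) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  ifelse(sim$status == paste0("case:", disease$name), "diseased", "not_diseased")
}

#' Analytic triage expectations under a synthetic configuration
#'
#' For one disease, computes the exact per-record probabilities of landing
#' in the negative / suspected / positive triage bands under the generative
#' mixture (log-normal tails for healthy and case branches; band records are
#' suspected with probability 1), and the implied expected counts with
#' binomial standard deviations. This is the oracle used to check that
#' simulated cohorts hit their configured rates.
#'
#' @param config a [synthetic_config()].
#' @param disease a [disease_definition()] present in the config (matched by
#'   name) or any definition over a panel marker.
#' @return list with `prob` (named: negative/suspected/positive), `expected`
#'   (counts = `n * prob`) and `sd` (binomial standard deviations).
#' @export
expected_triage_rates <- function(config, disease) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(disease, "disease_definition"))
  m <- disease$marker
  base <- config$baseline[config$baseline$analyte == m, ]
  s <- disease$screening_cutoff
  t <- disease$diagnostic_cutoff

  # P(suspected), P(positive) for marker ~ LN(mu + log(mult), sd)
  tail2 <- function(mult) {
    mu <- base$meanlog + log(mult)
    c(susp = stats::plnorm(t, mu, base$sdlog) - stats::plnorm(s, mu, base$sdlog),
      pos = 1 - stats::plnorm(t, mu, base$sdlog))
  }

  p_susp <- p_pos <- 0
  p_rest <- 1
  for (d in config$diseases) {
    mult <- if (m %in% names(d$effect)) d$effect[[m]] else 1
    tl <- tail2(mult)
    p_susp <- p_susp + d$prevalence * tl[["susp"]]
    p_pos <- p_pos + d$prevalence * tl[["pos"]]
    if (d$definition$name == disease$name) {
      # own band: marker drawn inside [s, t) => suspected surely
      p_susp <- p_susp + d$suspected_band_rate
    } else {
      tl0 <- tail2(1)  # other diseases' bands leave this marker at baseline
      p_susp <- p_susp + d$suspected_band_rate * tl0[["susp"]]
      p_pos <- p_pos + d$suspected_band_rate * tl0[["pos"]]
    }
    p_rest <- p_rest - d$prevalence - d$suspected_band_rate
  }
  tl0 <- tail2(1)
  p_susp <- p_susp + p_rest * tl0[["susp"]]
  p_pos <- p_pos + p_rest * tl0[["pos"]]

  prob <- c(negative = 1 - p_susp - p_pos, suspected = p_susp, positive = p_pos)
  list(prob = prob, expected = config$n * prob,
       sd = sqrt(config$n * prob * (1 - prob)))
}

#' Rate-matched synthetic scenario
#'
#' A ready-made three-disease configuration whose expected triage rates
#' match the published NTUH 2006-2011 tallies ([reference_screen_counts()]):
#' per-disease prevalence = positives / 347,312 and suspected-band rate =
#' suspected / 347,312, scaled to `scale` records. Case effect multipliers
#' (Phe x10, Met x10, C5OH x30) are large enough that cases exceed their
#' diagnostic cutoffs with probability ~1, matching the labelling convention
#' under which the published positives are confirmed cases.
#'
#' @param scale number of records (>= 1000).
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
make_scenario <- function(scale, seed = 0) {
  if (scale < 1000) {
    stop_nbs("scale must be at least 1000 for stable rare-event rates",
             class = "nbs_config_error")
  }
  counts <- reference_screen_counts()
  n_total <- attr(counts, "n_total")
  defs <- default_diseases()
  effects <- list(pku = c(Phe = 10), hypermethioninemia = c(Met = 10),
                  mcc = c(C5OH = 30))
  diseases <- lapply(counts$disease, function(dn) {
    row <- counts[counts$disease == dn, ]
    disease_scenario(defs[[dn]],
                     prevalence = row$positive / n_total,
                     effect = effects[[dn]],
                     suspected_band_rate = row$suspected / n_total)
  })
  synthetic_config(n = scale, diseases = diseases, seed = seed)
}
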