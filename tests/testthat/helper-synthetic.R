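# shared fixture builders (all generated in code, seeded)

tiny_panel <- function() analyte_panel(c("Phe", "Met", "Tyr", "Leu", "C16"))

# cohort from a values matrix with auto ids/years
mat_cohort <- function(values, panel = tiny_panel(), year = 2010,
                       confirmed = NULL) {
  values <- as.matrix(values)
  new_cohort(sprintf("s%03d", seq_len(nrow(values))),
             rep(year, nrow(values)), values, confirmed, panel)
}

# random valid cohort over the tiny panel
rand_cohort <- function(n, seed = 1, panel = tiny_panel(), years = 2006:2011) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n * length(panel), meanlog = 2, sdlog = 0.6),
                 n, length(panel))
  new_cohort(sprintf("r%04d", seq_len(n)),
             sample(years, n, replace = TRUE), vals,
             sample(c("diseased", "not_diseased", "unknown"), n, replace = TRUE),
             panel)
}

# single-disease synthetic scenario used by pipeline tests: rare PKU-like
# cases at x`effect` on Phe plus a healthy suspected band
pku_config <- function(n, prevalence = 1e-3, band = 5e-3, effect = 10,
                       seed = 0) {
  synthetic_config(n, diseases = list(
    disease_scenario(default_diseases()$pku, prevalence = prevalence,
                     effect = c(Phe = effect), suspected_band_rate = band)
  ), seed = seed)
}

# independent F-score oracle: raw sums only, no shared code with f_score()
brute_f_score <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  m1 <- sum(pos) / n1; m2 <- sum(neg) / n2
  m <- (sum(pos) + sum(neg)) / (n1 + n2)
  v1 <- sum((pos - m1)^2) / (n1 - 1)
  v2 <- sum((neg - m2)^2) / (n2 - 1)
  num <- (m1 - m)^2 + (m2 - m)^2
  if (v1 + v2 == 0) return(if (num == 0) 0 else Inf)
  num / (v1 + v2)
}

# independent subset-search oracle: re-enumerates every non-empty subset of
# the top-K ranked features with combn, scores each via evaluate_subset, and
# applies the selection rules by explicit scanning
brute_search <- function(ranked, K, tr_cohort, tr_lab, ev_cohort, ev_lab,
                         spec = classifier_spec()) {
  specs <- attr(ranked, "specs")[seq_len(K)]
  fs <- ranked$f_score[seq_len(K)]
  rows <- list()
  for (size in seq_len(K)) {
    for (combo in utils::combn(K, size, simplify = FALSE)) {
      ss <- evaluate_subset(specs[combo], tr_cohort, tr_lab, ev_cohort, ev_lab,
                            spec = spec)
      rows[[length(rows) + 1]] <- list(idx = combo, size = size,
                                       sens = ss[["sensitivity"]],
                                       spec = ss[["specificity"]],
                                       sum_f = sum(fs[combo]))
    }
  }
  best <- NULL
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (is.na(r$sens) || r$sens != 100 || is.na(r$spec)) next
    if (is.null(best)) { best <- c(r, list(i = i)); next }
    better <- (r$spec > best$spec) ||
      (r$spec == best$spec && r$size < best$size) ||
      (r$spec == best$spec && r$size == best$size && r$sum_f > best$sum_f)
    if (better) best <- c(r, list(i = i))
  }
  list(rows = rows, best = best)
}
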