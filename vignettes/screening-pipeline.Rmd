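---
title: "Two-stage classification for MS/MS newborn screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage classification for MS/MS newborn screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbscreen)
```

## The screening problem

Tandem mass spectrometry quantifies a panel of 35 metabolites (10 amino
acids, 25 acylcarnitines, all in μM) from one newborn dried blood spot.
Each screened disease is triaged on a single primary marker against two
thresholds: samples strictly above the *diagnostic cutoff* are positive
cases referred for a confirmation test; samples in the closed band from the
*screening cutoff* to the diagnostic cutoff are suspected cases recalled
for a repeat specimen; everything below is negative. The built-in
definitions are PKU (Phe > 85.02 / > 220 μM), hypermethioninemia
(Met > 54.12 / > 110 μM) and 3-MCC deficiency (C5OH > 0.56 / > 2.2 μM).

The cutoff scheme is deliberately conservative: nearly all of the suspected
band is healthy. The package's purpose is to train a classifier that
separates that band from true cases using the whole panel, and to measure
the false-positive reduction at unchanged sensitivity.

### Boundary semantics

Cutoff tables are usually printed with a bare ">", which leaves the
boundary ambiguous. `triage()` implements: positive iff value >
diagnostic cutoff; suspected iff screening ≤ value ≤ diagnostic; negative
otherwise. A value exactly at either cutoff is therefore *suspected* — the
safe direction for a screening programme, since boundary samples stay
flagged. The convention is attached to every triage result as a `boundary`
attribute so downstream consumers need not guess.

## The fitting pipeline (`nbs_screen()`)

The training pool is the set of cutoff-flagged records; confirmed cases
form the positive class, the remaining flagged records the suspected
(negative) class. This mirrors how a retrospective screening archive is
labelled: only flagged samples ever received confirmation testing, so only
they carry reliable labels.

### Primary weights

For each analyte, `D = median(positives) − median(suspecteds)` (μM). The
signed primary weight is `D / scale`, where `scale` is the interquartile
range of the analyte over the pooled flagged records. The median/IQR pair
was chosen over mean/SD deliberately: analyte concentrations are heavy
right-tailed, and case values can be an order of magnitude above baseline,
so moment-based statistics would be dominated by a handful of extreme
cases. When an analyte's pooled IQR is zero the scale falls back to the
pooled standard deviation, then to 1; the fallback used is recorded in the
`scale_type` column so degenerate analytes are auditable. The weight's sign
always equals the sign of `D`. The normalizer is isolated inside
`compute_primary_weights()`, so swapping in an alternative scale is a
one-line change.

The top `k_markers = 3` positive-weight and top 3 negative-weight analytes
are the selected markers. Fewer are returned when fewer analytes carry
weights of that sign (with rare diseases it is common for only two analytes
to show positive weights); zero-weight analytes are never selected.

### Manifested features

Derived features are built over the selected markers: every unordered
pairwise product over the union of both marker lists, plus every
positive/negative ratio — `choose(p + n, 2) + p·n` features, i.e. 24 for a
full 3 + 3 selection. Product operands are stored in sorted order so
`A×B` and `B×A` are one feature, and the display dialect is the one used in
screening reports: `Phe`, `Leu×Tyr`, `Orn/C16`. Reported marker sets for
this methodology show both within-list products and cross ratios, but no
published enumeration rule reproduces the reported feature totals exactly
(17 and 11 manifested features where this enumeration yields 24 and 16);
rather than silently matching totals, the package documents its rule and
keeps it behind `build_manifested_features()` so an alternative enumeration
is pluggable. No other transformations (logs, z-scores,
multiple-of-median) are applied — products and ratios are the entire
derived-feature vocabulary.

Ratios are guarded: denominators below `eps = 1e-6` μM are replaced by
`eps`, and every evaluation matrix carries an `n_guarded` attribute so QC
can count guarded cells. The guard value is far below the smallest
physiological concentration on the panel, so it only fires on true zeros.

### F-score ranking

Candidate features (35 raw analytes plus the manifested features) are
ranked by the standard two-class F-score

$$F = \frac{(m^+ - m)^2 + (m^- - m)^2}{s_+^2 + s_-^2}$$

with class means $m^\pm$, overall mean $m$, and class sample variances
(n−1 denominators). This definition is written out because the name
"F-score" is overloaded; the implementation is pinned to this exact form
and cross-checked in the tests against an independent raw-sums
implementation. Degenerate features are well-defined: both variances zero
with equal means gives 0, with unequal means gives `Inf` (a perfectly
separating constant feature, ranked first). F-scores are computed on raw
concentrations — the F-score is scale-dependent in general, but
standardization happens later, inside the classifier, where it matters.

Ties are broken by a canonical feature order (raw before product before
ratio, then C-locale lexicographic), so rankings are identical across
platforms and runs. The top `top = 20` features proceed.

### Exhaustive subset search

Every non-empty subset of the top `max_rank` ranked features is used to
train an RBF-kernel support vector classifier and scored on an evaluation
split; the winner is chosen by, in order: (1) sensitivity exactly 100%,
(2) maximum specificity, (3) fewest features, (4) highest summed F-score,
(5) earliest in enumeration order (subsets by size, then lexicographic).
The complete per-subset ledger is retained in the result for audit, and
"no subset reached 100% sensitivity" is an explicit result, not an error.

Two open choices were resolved as follows:

* **What data the per-subset metrics use.** The methodology's description
  of this step does not pin down an evaluation protocol, and resubstitution
  would make the 100%-sensitivity criterion nearly vacuous (large-C RBF
  classifiers can memorize the training pool). `nbs_screen()` therefore
  scores each subset on a seeded stratified 80/20 internal split of the
  training pool (`split_frac = 0.2`); both splits are exposed as arguments
  to `search_optimal_subset()` so k-fold or external splits are possible.
* **Search breadth.** A full search over 20 features trains
  $2^{20}-1 \approx 10^6$ classifiers. That is supported but gated behind
  `full_search = TRUE`; the default `max_rank = 10` (1023 subsets) is the
  desk-scale default, and the package's own tests and examples use 5–8.

### The classifier

`train_classifier()` fits a C-classification SVM with RBF kernel via
libsvm (package `e1071`), with slack `C = 100` and `gamma = "auto"` resolving
to 1/d, d the number of input features — the defaults of the methodology
this package implements. Features are standardized with the training
split's mean and standard deviation before fitting (zero-variance features
get unit scale); without this, μM-scale mixtures of raw analytes and
product features make the RBF distances numerically degenerate. The scaler
is stored in the model and applied at prediction, so a trained model is a
self-contained object. No other kernels and no hyperparameter tuning are
offered: the method's contract is a fixed-C, fixed-γ RBF machine, and
widening that contract would change what is being evaluated.

### Cross-validated model choice

The winning subset is refit under stratified `folds = 5`-fold
cross-validation (seeded fold assignment; every fold receives at least one
member of each class). Each fold's model is scored on its held-out fold and
the model with the highest held-out specificity subject to 100% held-out
sensitivity is returned — the *fold model itself*, which is the literal
reading of "the optimal model is obtained from the 5 different models".
`refit = TRUE` instead refits the chosen configuration on all records,
for users who prefer the conventional refit; the cross-validation table is
kept either way. When no fold reaches 100% sensitivity the fallback is
highest sensitivity, then specificity, then fold order. If a class has
fewer members than `folds`, `crossvalidate_optimal_model()` refuses
(stratification would be undefined); the `nbs_screen()` wrapper instead
reduces the fold count to the largest feasible value and records it in
`folds_used`, because rare-disease pools with ~10 confirmed cases are the
norm, not the exception.

### Two-stage prediction

On new samples, `two_stage_predict()` applies the cutoff gate first:

* below the screening cutoff → screen-negative, classifier never consulted;
* above the diagnostic cutoff → screen-positive, classifier never
  consulted;
* in the suspected band → the classifier decides.

The first rule reflects deployment reality (below-cutoff samples are never
recalled, so the model must not be able to flag them). The second rule is a
deliberate design decision: diagnostic-cutoff exceeders are positive cases
*by definition* of the triage scheme and proceed to confirmation testing
regardless of any classifier, and a screening programme must never be less
sensitive than the cutoff scheme it augments. With small confirmed-case
pools this matters in practice: an RBF decision boundary fit on ~10 cases
sits near the midpoint between the sampled cases and the band, and a new
case with a marker above the diagnostic cutoff but below the sampled cases
would otherwise be downgraded — a false negative the cutoff scheme could
not have produced. Both alternative behaviours remain available
(`classify_band_only = FALSE` sends all flagged records through the
classifier; `classify_all = TRUE` bypasses the gate entirely) for
sensitivity analysis.

### Metrics and reporting

Confusion counts always conserve the evaluated cohort
(TP + TN + FP + FN = n). Sensitivity, specificity and accuracy are
percentages kept at full precision internally; rounding (half away from
zero, 3 decimals) happens only at the reporting layer, and undefined
ratios (zero denominators) are reported as not-applicable em-dashes, never
as 0. The current-method baseline counts every triage-flagged record as a
screen positive. Because archival comparisons sometimes publish only the
proposed method's true negatives, `derive_current_confusion()` recovers
the cutoff scheme's TN as (proposed TN + proposed FP) − current FP under
the shared-denominator, no-false-negative assumptions.

## The synthetic cohort generator

`simulate_cohort()` draws each record's status from one categorical
distribution — case of disease *i* (probability = prevalence), healthy
suspected-band contaminant for disease *i* (probability = band rate), or
plain healthy — then draws all 35 analytes from per-analyte log-normal
baselines, optionally correlated on the log scale. Cases multiply their
effect analytes; band records have their disease's marker redrawn
log-uniformly inside the screening band. Truth labels come from the
generative branch, never from cutoffs, so the cutoff scheme's own error
rates are measurable. Identical seed and config give byte-identical
cohorts.

Defaults, chosen once as plausible values for this assay rather than fitted
to any dataset:

* Log-normal baselines, because concentrations are positive and
  right-skewed. Medians are physiologic dried-blood-spot values (e.g. Phe
  45 μM, Met 22 μM, C5OH 0.2 μM); `sdlog` is 0.25 generally and 0.15–0.20
  for the three screening markers, tight enough that the healthy tail
  essentially never crosses a screening cutoff — which makes the suspected
  band an explicit, controllable model component (the band *is* the
  phenomenon the classifier exists to clean up) rather than an accident of
  the tail.
* `make_scenario(scale)` builds a three-disease configuration whose
  expected triage rates match the published 2006–2011 screening tallies:
  prevalence = positives/347,312 and band rate = suspected/347,312 per
  disease, with case effects ×10 (Phe), ×10 (Met) and ×30 (C5OH) so that
  cases exceed their diagnostic cutoffs with probability ≈ 1, matching the
  labelling convention under which published positives are confirmed
  cases. `expected_triage_rates()` computes the exact per-band
  probabilities implied by a configuration (log-normal tails for every
  branch of the mixture), and the tests require simulated triage counts to
  sit within 4 binomial standard deviations of those expectations.
* Inter-analyte correlation defaults to none; real panels are correlated
  (acylcarnitines co-vary), but realistic magnitudes are not derivable
  from published summaries, so correlation is available as explicit config
  (`|ρ|` up to ~0.3 is what we would call modest) and clearly synthetic.

What the generator does **not** emulate: assay drift and batch effects,
covariates (birth weight, gestational age, age at sampling), maternal
conditions that elevate a newborn's marker, multi-marker disease
signatures beyond the configured effect vectors, and real-world label
noise in confirmation outcomes. Consequently, passing tests demonstrate
that the pipeline recovers planted signals under its own stated
assumptions — they do not certify performance on real screening archives.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on cohorts
of 4,000–50,000 synthetic records with `max_rank` 5–8 (31–255 subsets per
search), and the parameter-recovery study uses 20 replicate seeds at
n = 10,000, prevalence 10⁻³, effect ×10 — sizes chosen so a complete run
is a coffee-break on a laptop while keeping ≥ 30 flagged records per fit.
Every stochastic operation (simulation, splits, fold assignment) takes an
explicit integer seed, defaults to 0, and records it in its output;
rerunning any step with the same seed reproduces identical artifacts
byte-for-byte.

## Known limitations

* The signed primary-weight normalizer is a declared design choice; other
  robust scales would reorder near-tied analytes.
* The per-subset search trains one classifier per subset per call; at
  `max_rank = 20` that is ~10⁶ fits and hours of CPU, which is why the
  full search sits behind a flag.
* The 100%-sensitivity criterion is brittle by construction: with only a
  handful of confirmed cases in the evaluation split, one misclassified
  case discards a subset. This is faithful to the methodology, but users
  with larger archives should consider the k-fold variant of the internal
  split.
* Single-marker diseases only: the triage definitions assume one primary
  marker per disease. Diseases screened on marker ratios would need a
  `FeatureSpec`-valued marker, which the data model does not currently
  allow.
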