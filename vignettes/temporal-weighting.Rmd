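---
title: "Learning temporal weights of clinical events with random-forest importance"
author: "tempoRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning temporal weights of clinical events with random-forest importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempoRF)
```

## The problem

Adverse drug events (ADEs) are badly under-reported in electronic health
records (EHRs). A practical mitigation is to train a classifier that flags
patients whose records look like they should have carried an ADE diagnosis:
positives are patients with an ADE-specific code, negatives are patients
with a *similar* (same three-level ICD-10 stem) but non-ADE code, and
features are counts of clinical events — diagnoses, drugs and clinical
measurements — observed in the 90 days before the index (ADE) date.

Clinical events are time stamped, and when an event happened matters: a
blood-pressure measurement the day before a drug-induced hypotension
diagnosis is not the same evidence as one three months earlier. The classic
way to encode this is a *pre-assigned* temporal weight, a fixed decay curve
of the day offset $n$:

$$ w = f(n) = \frac{1}{n}, $$

with same-day events ($n = 0$) receiving the maximal weight 1, so all
weights lie in $(0, 1]$ and decrease monotonically out to the 90-day
horizon. The reciprocal curve is the best-performing member of the family
of monotone decay curves studied in earlier work, and it is the only
pre-assigned curve this package implements.

Pre-assigned weights encode *recency only*. The premise of this package is
that the weight of an event should reflect its *informativeness* at each
time, and that this can be learned from the data:

1. Split the 90-day history into 12 windows ending at days
   1, 2, 3, 4, 5, 6, 7, 14, 21, 30, 60, 90, each window excluding the days
   of the previous one, and treat the same event code in different windows
   as different count features (the *Bag of Binned Events*).
2. Fit a standard random forest on the binned matrix and read off the Gini
   variable importance of every (code, window) column. The normalized
   importances are the learned weights.
3. Apply the weights by one of two strategies:
   * **Weighted Aggregation (WA)** — multiply each window count by its
     weight and sum over windows, collapsing back to one feature per code;
   * **Weighted Sampling (WS)** — keep the binned features and use the
     weights as the probabilities with which candidate splitting features
     are drawn at each node of an enriched random forest.

Each strategy exists in a pre-assigned (PWA, PWS) and a learned (LWA, LWS)
variant; the package's evaluation harness reproduces the four-arm
comparison, the tree-versus-ensemble diversity decomposition, and the
granularity study (weights per event code, per event type, or per window).

## The weighted forest

The forest is written from scratch (C++ core) because the weighted
candidate sampling is the method itself, not a detail a stock
implementation exposes:

* Gini-split CART trees, grown fully (`min_node_size = 1`) on bootstrap
  replicates of the training rows; 500 trees by default.
* At every node, `mtry` (default $\lfloor\sqrt{p}\rfloor$) distinct
  candidate features are drawn by successive draws without replacement,
  each draw proportional to the remaining probabilities. With uniform
  probabilities this is exactly the standard random forest, which is how
  weights are *learned*; with non-uniform probabilities it is the enriched
  forest used to *apply* them (PWS/LWS). Zero-probability features are
  never drawn, matching the reading of a zero Gini importance as "useless
  or never selected": by default no smoothing floor is added, though
  `to_sampling_probs(..., floor =)` provides one.
* The implementation draws candidates by rejection from the static
  cumulative-weight table (a draw that hits an already-selected feature is
  redrawn). The conditional distribution of each new feature is
  proportional to the remaining mass, so this is identical in law to
  renormalizing after every draw, at $O(\texttt{mtry}\log p)$ per node
  instead of $O(p \cdot \texttt{mtry})$; a renormalized exact scan takes
  over after a rejection cap so concentrated weight vectors cannot stall.
* Thresholds are midpoints between consecutive distinct values. Split ties
  break to the lowest column in manifest order, then the lowest threshold;
  leaf-vote ties and ensemble score ties (exactly 0.5) resolve to the
  negative class. These rules make fits bit-reproducible.
* Each tree seeds its own RNG substream from (seed, tree index), so the
  forest is identical regardless of fitting order.
* Gini importance accumulates
  $\Delta_j = (n_j/n)\,[G_j - (n_L/n_j)G_L - (n_R/n_j)G_R]$ over internal
  nodes, averaged over trees and normalized to sum to one.

Because binned EHR count matrices are overwhelmingly zero, the split search
treats the zero block of a node specially (counted, not sorted) and sorts
only the non-zero entries of each candidate column; this is what keeps
500-tree fits on ~18,000-column matrices in the seconds range.

## Learned-weight plumbing

`learn_event_weights()` always fits the *uniform* forest — weights are
learned with the standard algorithm and only applied through the enriched
one. Granularity coarsening (`aggregate_weights()`) takes arithmetic means
within (type, window) or window groups, which keeps all levels on a common
scale and makes the expanded column weights conserve the mean; coarser
tables expand back onto the columns before use. For aggregation the learned
weights are max-scaled onto $[0, 1]$ (`scale_for_aggregation()`) to mirror
the pre-assigned range; any positive rescaling is equivalent for sampling
but not for aggregation, so the scale is a genuine design choice and the
max-scaling convention is recorded here. For the pre-assigned sampling
arm, each window's representative day is its upper boundary (a midpoint
would be the obvious alternative; the upper boundary is the single
deterministic choice consistent with window 1 having weight 1).

Weight learning happens *inside each training fold* of the evaluation
protocol. The alternative — learning once on the full data — leaks label
information from test folds into the sampling probabilities, so the
leak-free protocol is the default here.

## The synthetic cohort generator

The real corpora behind this method are ethics-restricted EHR extracts, so
the package ships a generator that emulates their stated structure rather
than any real vocabulary: 1,500 codes across the three event types, a
90-day horizon, 30 % positives, and independent Poisson occurrence counts
per (patient, code, window) with expected count
`baseline_rate × window_width / 91`, so `baseline_rate` is the expected
number of occurrences of a code over the whole history. Informative
(code, window) pairs multiply that rate by `effect_multiplier` in positive
patients only; occurrence days are uniform within their window.

Defaults (chosen once, with a power argument, and not revisited):

* `baseline_rate = 0.5` gives > 95 % zero cells in the binned matrix, the
  sparsity regime the method targets.
* `informative_window_profile = 8:12`: the single-day windows 2–7 carry an
  expected per-cell count of only ~0.005 at this baseline, far too few
  occurrences for *any* importance measure to detect at 600 patients, so
  signal is planted in the multi-day windows (widths 7–30 days). This also
  puts the planted signal exactly where the recency-biased pre-assigned
  weights (1/14 … 1/90) down-weight hardest, which is the regime the
  method was designed for: informativeness that recency does not predict.
* `n_informative = 20` of 18,000 columns — the "small informative
  fraction" under which enriched sampling is expected to help.

What the generator does **not** emulate: realistic ICD/ATC vocabularies,
comorbidity correlation between codes, visit-level clustering of events,
and the extreme (≤ 1 %) imbalance of some real ADE datasets. Passing
benchmarks on these cohorts therefore demonstrate the machinery and the
qualitative mechanism, not clinical performance.

## Evaluation harness and statistics

`stratified_cv()` shuffles within class and deals round-robin (5 folds, 2
iterations by default); every class must have at least `k` members.
Metrics follow the conventions of the field: accuracy in percent under the
voting threshold, AUC as the pairwise concordance probability (ties count
one half), and AUPRC as average precision (no PR-space interpolation,
which is over-optimistic). Diversity is reported as average individual-tree
error minus ensemble error on the held-out fold.

Comparisons between two arms use an exact two-sided Wilcoxon signed-rank
test (full null distribution by convolution up to 25 non-zero pairs;
normal approximation with tie correction beyond, no continuity
correction; all-zero differences give p = 1 by convention). Three-arm
granularity comparisons use the Friedman test on within-dataset ranks
(higher metric = rank 1) followed by Bergmann–Hommel post-hoc adjustment,
which for three hypotheses amounts to multiplying the smallest raw p by 3
and enforcing monotonicity — the exhaustive sets for three methods are the
full triple and the singletons.

## Problem sizes used by the shipped checks

The packaged tests run the benchmark at the generator's default scale
(600 patients × 18,000 binned columns) with 100-tree forests, ten dataset
seeds, and one 5-fold iteration per dataset; replication across the ten
seeds substitutes for the second fold iteration. Weight recovery uses the
default 500-tree forests on five seeds. These sizes keep the whole suite in
the minutes range on a single core while leaving every qualitative
comparison at the study's native dimensionality.

## Known limitations

* Binary classification only; no regression trees, out-of-bag error, or
  permutation importance.
* Learned weights come from one importance measure (Gini); importance
  biases toward high-cardinality features are inherited.
* The aggregation scale for learned weights (max-scaling) and the
  representative day of a window (upper boundary) are package choices
  where the method description is silent; both are isolated behind
  `scale_for_aggregation()` and `preassigned_window_weights()`.
* Day-0 events are included in window 1. Whether same-day events belong in
  the history at all is ambiguous (they receive pre-assigned weight 1, but
  a same-day event may post-date the ADE within the day); excluding them is
  a one-line filter on the event table.
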