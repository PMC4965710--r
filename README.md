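# tempoRF

Temporal weighting of clinical events for adverse drug event (ADE)
detection in longitudinal electronic health records (EHRs), with weights
**learned** from random-forest Gini variable importance instead of
pre-assigned from time stamps alone.

ADEs are under-reported in EHRs; a classifier can flag patients whose
90-day history of diagnoses, drugs and clinical measurements looks like an
unreported ADE. Event counts are time stamped, and the standard way to use
that temporality is a pre-assigned decay weight for an event observed *n*
days before the index event,

    w = f(n) = 1/n        (day-0 events receive the maximal weight 1),

which encodes recency but not informativeness. tempoRF instead

1. bins the 90-day history into 12 windows (ending at days
   1, 2, 3, 4, 5, 6, 7, 14, 21, 30, 60, 90), treating the same event code
   in different windows as different count features ("Bag of Binned
   Events");
2. learns a weight for every (code, window) feature as its normalized Gini
   importance in a standard random forest, optionally coarsened to
   per-event-type or per-window granularity;
3. applies the weights either by **weighted aggregation** (weighted sums
   over windows, one feature per code) or by **weighted sampling** — an
   enriched random forest whose per-node candidate features are drawn with
   probabilities proportional to the weights.

The four arms (PWA/LWA/PWS/LWS = pre-assigned/learned × aggregation/
sampling) are compared through stratified cross-validation with accuracy,
AUC, AUPRC, a tree-versus-ensemble diversity decomposition, and a
Wilcoxon / Friedman / Bergmann–Hommel statistical chain. The weighted
forest (Gini-split CART trees, bootstrap replicates, per-node weighted
candidate sampling, deterministic per-tree RNG substreams) is implemented
from scratch with a C++ core. Because the EHR corpora behind this method
are ethics-restricted, the package ships a synthetic cohort generator that
plants window-specific signal into sparse Poisson count features at the
study's dimensionality.

## Worked example

```r
library(tempoRF)

cfg <- simulation_config(n_patients = 300,
                         n_codes_per_type = c(diagnosis = 120, drug = 100,
                                              measurement = 80),
                         n_informative = 10, effect_multiplier = 4,
                         seed = 2026)
sim <- generate_cohort(cfg)          # 45,284 events, 300 patients, 90 positive

binned <- bin_events(sim$events, sim$cohort)   # 300 x 3600 sparse counts
weights <- learn_event_weights(binned, sim$cohort$label,
                               forest_params(n_trees = 300, seed = 1))
weights[order(-weights$weight), ][1:5, ]
#>      key window      weight
#>  MEA0012     11 0.011475204
#>  DIA0093     11 0.011214333
#>  MEA0080     11 0.010077591
#>  DRG0084      9 0.007136665
#>  DRG0092     10 0.007096948
recovery_score(weights, sim$truth, k = 10)
#> [1] 0.7
```

The learned weights put planted (code, window) pairs at the top: 7 of the
10 planted pairs sit among the 10 largest weights, and each weight is that
column's share of the forest's total Gini impurity decrease.

Comparing the two sampling arms under 5-fold cross-validation (2
iterations, 100 trees):

```r
plan <- stratified_cv(sim$cohort$label, k = 5, iterations = 2, seed = 3)
params <- forest_params(n_trees = 100, seed = 4)
pws <- run_strategy("PWS", sim$events, sim$cohort, params = params, plan = plan)
lws <- run_strategy("LWS", sim$events, sim$cohort, params = params, plan = plan)
#> PWS: accuracy 68.8%  AUC 0.562  AUPRC 0.406  diversity 0.088
#> LWS: accuracy 77.3%  AUC 0.789  AUPRC 0.675  diversity 0.104
```

Learned-weight sampling dominates pre-assigned sampling on every metric
here because the informative events live in the multi-day windows that the
recency-biased 1/n weights sample almost never — exactly the regime the
method targets. `run_benchmark()` scales this comparison to many datasets
and attaches the significance tests; `trf_main()` (or the
`inst/cli/tempoRF` script) exposes `simulate`, `featurize`,
`learn-weights`, `train`, `evaluate` and `benchmark` subcommands.

See `vignettes/temporal-weighting.Rmd` for the model, the numerical
conventions (tie-breaks, thresholds, RNG substreams), the generator's
assumptions, and known limitations.

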