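# theatreflow

Estimating how the composition of a surgeon's operating list relates to
operation duration, from routinely collected theatre records.

An operating list is a natural experiment in surgical warm-up and task
switching. theatreflow is for biostatisticians and health-services
researchers who want to quantify three effects on (log) operating time:

* **absolute list order** — each further position on the list;
* **procedure-specific list order** — each repetition of the *same*
  procedure on the list (the warm-up effect);
* **switching** — following a *different* procedure than the previous case
  (the task-switching cost).

The package covers the whole chain: cleaning raw electronic records with an
auditable exclusion flow, reconstructing theatre lists per surgeon/day and
coding every case with its absolute number `A`, procedure-specific number
`S` and switch flag `W`; a linear mixed-effects model of log duration; a
randomized exact-matched paired analysis; and a synthetic record generator
so the full pipeline is validated by parameter recovery.

## The model and the matched design

All analysis is on the natural log of duration, where additive effects are
proportional changes. The primary model, fitted by REML (lme4):

    log y = α + β_abs (A − 1) + β_spec (S − 1) + β_sw W + b_cell + ε,
    b_cell ~ N(0, τ²) per (procedure × age group × ASA grade) cell,
    ε ~ N(0, σ²)

The cell random intercepts absorb case-mix baselines without assuming any
relationship between age, ASA and duration. A coefficient β is reported as
a percent change `100·(exp(β) − 1)`. The same model on log length of stay
gives the secondary outcome.

The matched analysis pairs, within each procedure, cases at
procedure-specific position 1 with position-2 cases of identical age group
and ASA grade: position-1 cases scanned in random order, each choosing
uniformly among remaining compatible candidates, every record used at most
once. Exact cell matching makes the pairing maximal (min(n₁, n₂) pairs in
every cell, for any seed); the effect is the mean within-pair difference in
log duration with a paired *t* interval.

## Worked example

```r
library(theatreflow)

cfg   <- generator_config(n_lists = 2000, seed = 42)  # ~8500 records
raw   <- generate_dataset(cfg)
cleaned <- clean_records(raw)
cleaned$summary
#> Exclusion summary
#>   input records        8498
#>   no surgeon id        156
#>   no start time        18
#>   duplicates           0
#>   non-positive duration 0
#>   invalid category     0
#>   retained             8324

coded <- code_records(cleaned$records)
switch_fraction(coded)
#> [1] 0.518

fit_lmm(coded, "duration")
#> Log-duration mixed model: 8324 observations, 260 cells
#>   cell SD (tau) 0.7243, residual SD (sigma) 0.3555
#>   absolute_order  -0.37% (95% CI -0.86 to +0.12), P 0.141
#>   specific_order  -0.60% (95% CI -1.92 to +0.73), P 0.375
#>   switch          +7.60% (95% CI +5.49 to +9.74), P <0.001

res <- match_pairs(coded, k = 1, seed = 1)
res
#> Matched 1881 pairs (positions 1 vs 2) from 5592 and 1903 candidates (seed 1)
paired_effect(res)[, c("pct", "pct_low", "pct_high", "p_value", "n")]
#>     pct pct_low pct_high p_value    n
#>   -3.09   -5.34   -0.795 0.00861 1881
```

Reading the output: the cleaning summary partitions the raw rows; about
52% of coded cases follow a different procedure than their predecessor;
each switch lengthens operations by about 7.6% in this simulation
(generated with a 6.48% true cost), while order effects of a few tenths of
a percent are too small to resolve at 8000 records — they need the
40 000-record default scale. The matched analysis estimates a 3.1%
(95% CI 0.8 to 5.3) saving for the second same-procedure case relative to
the first.

Everything composes: `per_procedure_fits()` and `per_procedure_matched()`
give forest-table input per procedure (`forest_table()`), `classify_records()`
attaches method/complexity strata for `stratified_matched()`,
`position_profile()` tabulates mean duration by repetition number, and
`run_pipeline()` runs the whole chain from a config to CSV/JSON artifacts
plus a replayable manifest.

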