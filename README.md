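# abstainr

Selective prediction for binary biomedical classifiers: find the abstention
interval on the probability scale that best trades the quality of the
decisions made against the number of decisions made, and trichotomize
predictions into **positive / negative / rejected**.

## Why

Biomedical classifiers routinely face heavy class imbalance, and samples
scoring near the decision threshold are decided almost at random — a real
problem when a wrong call means a wrong treatment. Classification with a
reject option declines those calls instead: scores inside an interval
[L, U] are *rejected* (deferred to a human), scores at or above U are
positive, at or below L negative. The interval is parameterized by an
anchor *a* (offset of its center from the 0.5 threshold) and half-width
*h*:

    L = 0.5 + a − h,    U = 0.5 + a + h

A symmetric interval (a = 0) sits on the threshold; an *asymmetric* one
shifts the gray zone toward the region where the case and control score
distributions actually overlap, which under class imbalance is rarely
centered at 0.5.

The interval is chosen by exhaustive grid search to maximize

    objective = MCC × coverage

where MCC is the Matthews correlation coefficient of the classified
samples — a 2×2-confusion summary that stays informative under imbalance —
and coverage is the fraction of samples classified rather than rejected.
(MCC, coverage) is a Pareto trade-off; the package exposes the full front
and uses the product as the scalarization that picks one operating point.
With h = 0 in every default grid, abstaining is never selected unless it
beats doing nothing.

## Worked example

```r
library(abstainr)

# synthetic scores: 10% cases, Beta(8,2) vs Beta(2,8) class-conditional
# score distributions overlapping around 0.5
scores <- simulate_scores(score_sim_config(n = 2000, positive_fraction = 0.1,
                                           seed = 42))

abstention_cost(scores, half_width = 0)   # the plain 0.5-threshold classifier
#>           mcc size_fraction
#>     0.8909939     1.0000000

fit <- fit_asymmetric(scores)
fit
#> Asymmetric abstention fit (336 grid points evaluated)
#>   best interval [0.545, 0.645] (anchor 0.0947, half-width 0.050)
#>   MCC 0.967, coverage 0.987, rejected 1.3%, objective 0.954
#>   Pareto front: 29 non-dominated point(s)
```

Rejecting 1.3% of the samples — those scoring in [0.545, 0.645], a gray
zone shifted *above* the threshold because the rare positive class owns
that region — raises the MCC of the decisions actually made from 0.891 to
0.967. `fit$grid` holds all 336 evaluated `(half_width, anchor, mcc,
size_fraction, objective)` points (heatmap-ready), `fit$pareto_front` the
non-dominated ones, and `classify_with_abstention(scores$score,
fit$interval)` applies the fitted rule.

The full pipeline from a feature table — stratified split, logistic (or any
pluggable) base classifier, then none/symmetric/asymmetric abstention on
the held-out scores — is `run_experiment()`; `scenario = "balanced"`
down-samples the majority class first.

## Command line

```sh
Rscript inst/cli/abstain.R simulate --n 1831 --positive-fraction 0.096 --seed 7 --out sim/
Rscript inst/cli/abstain.R fit --input sim/scores.csv --mode asymmetric \
    --replication-profile --out fit/
Rscript inst/cli/abstain.R experiment --input data.csv --scenario both --out exp/
```

Every command writes its fully resolved configuration (`config.json`) next
to its outputs, so any run is reproducible from its output directory.
`--replication-profile` pins the search to the published study grids:
half-widths 0, 0.01, …, 0.15 and 20 endpoint-inclusive anchors on
[−0.2, 0.2].

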