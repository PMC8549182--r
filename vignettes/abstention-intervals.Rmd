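---
title: "Abstention intervals for binary biomedical classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstention intervals for binary biomedical classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abstainr)
```

## The problem

A probabilistic binary classifier for a medical question — is this mass
malignant, is this cardiotocogram pathologic — produces a positive-class
probability $p \in [0,1]$ per sample and, by default, decides positive when
$p \ge 0.5$. The score distributions of cases and controls overlap in
practice, so samples near the threshold are decided almost at random, and in
a clinical setting a confidently wrong call can be much worse than no call
at all. Selective prediction (classification with a reject option) addresses
this by trichotomizing the output: positive, negative, or *rejected*, the
last meaning "refer to a human". The rejected region is an **abstention
interval** $[L, U]$ on the probability scale: a sample is classified
positive when $p \ge U$, negative when $p \le L$, and rejected when
$L < p < U$.

`abstainr` finds the best such interval from labeled scores. Intervals are
parameterized by an *anchor* $a$ (the offset of the interval's center from
0.5) and a *half-width* $h \ge 0$:

$$L = 0.5 + a - h, \qquad U = 0.5 + a + h.$$

A symmetric interval has $a = 0$; a nonzero anchor shifts the gray zone
toward one class, which matters under class imbalance, where the optimal
operating region is rarely centered on 0.5.

## The objective

Widening the interval removes hard samples, so it tends to raise the
quality of the decisions actually made while lowering the number made.
These are two conflicting goals, a Pareto problem in the plane of

* **MCC** — the Matthews correlation coefficient of the classified samples,
  $$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$
  chosen because it stays informative under heavy class imbalance where
  accuracy saturates; and
* **coverage** (fractional size) — the fraction of samples classified
  rather than rejected.

`pareto_front()` returns every evaluated $(\mathrm{MCC}, \text{coverage})$
point not dominated in both coordinates. To select a single operating
point the package scalarizes with the product
$\text{objective} = \mathrm{MCC} \times \text{coverage}$, which equals the
plain classifier's MCC when nothing is rejected, is driven to 0 when
everything is, and can only exceed the no-abstention value when the MCC
gain outweighs the coverage loss. The product's argmax is always on (or
tied with) the Pareto front.

## The optimizers

`fit_symmetric()` runs a 1-D grid search over half-widths,
`fit_asymmetric()` a 2-D search over the Cartesian product of half-widths
and anchors. The search is an exhaustive evaluation of the grid — the
objective is a step function of $(a, h)$ (it changes only when a bound
crosses a score), so there is nothing smooth to exploit, and the grids are
small enough that exhaustive search is exact by construction. Defaults, and
why:

* **Half-widths**: the half-open sequence $0, 0.01, \ldots < 0.16$, i.e. 16
  values up to $h = 0.15$ (an interval covering 30% of the probability
  range — abstaining more than that is rarely a useful operating point, and
  the grid always contains $h = 0$, so doing nothing is always a candidate).
  Units are probability; the hard ceiling is $h = 0.5$.
* **Anchors**: 20 evenly spaced values on $[-0.2, 0.2]$, *both endpoints
  included*. With an even count this spacing (step $0.4/19 \approx 0.021$)
  skips 0, so by default a zero anchor is injected
  (`include_zero_anchor = TRUE`, 21 anchors): that guarantees the symmetric
  search is a subset of the asymmetric one, hence
  `fit_asymmetric()`'s objective is never below `fit_symmetric()`'s. The
  strict 20-anchor grid without the injected zero is available as the
  *replication profile* (`include_zero_anchor = FALSE`, or
  `--replication-profile` on the command line).

Numerical choices worth knowing:

* **Boundary equality classifies.** Scores exactly at $L$ or $U$ are
  labeled, not rejected; with $h = 0$ the rule reduces exactly to
  $p \ge 0.5 \Rightarrow$ positive. This maximizes coverage and makes the
  zero-width point identical to the plain classifier.
* **Degenerate MCC is 0.** If any factor of the MCC denominator is zero
  (abstention emptied a predicted or true class, or everything was
  rejected), the MCC — and hence the objective — is defined as 0. This
  keeps the search well-defined on every grid point.
* **Ties break toward least abstention.** Among equal objectives the
  optimizer prefers the smallest half-width, then the anchor nearest 0,
  then the lower anchor; results are therefore deterministic,
  bit-identical across runs.
* **Clipping.** Bounds outside $[0,1]$ are clipped with a warning; the
  default grids never clip (maximum $|a| + h = 0.35$).

## Synthetic data and what it does (not) show

`simulate_scores()` draws labels Bernoulli($\pi$) and scores from two
class-conditional Beta distributions — Beta because it lives on the
probability scale, takes any skew, and has a closed-form CDF. The defaults
model the regime the method targets: controls Beta(2, 8) (mean 0.2), cases
Beta(8, 2) (mean 0.8), overlapping around 0.5, with $\pi = 0.1$ — roughly
one case in ten, the imbalance of screening-type datasets. At those
settings the plain 0.5-threshold classifier has a population MCC of about
0.90, leaving visible headroom for abstention.

Because the mixture has closed-form CDFs, the expected objective of any
interval is available analytically: `population_objective()` computes the
population confusion *rates*

$$TP = \pi(1 - F_1(U)),\quad FN = \pi F_1(L),\quad
  FP = (1-\pi)(1 - F_0(U)),\quad TN = (1-\pi)F_0(L)$$

and applies the (scale-invariant) MCC formula to them. This oracle lets the
test suite check *parameter recovery*: on samples of $n = 10{,}000$ the
grid point selected by `fit_asymmetric()` must have a population objective
within one grid step's objective difference of the grid's population
optimum (operationally: at least the smallest population objective found in
the optimum's immediate grid neighborhood) in at least 9 of 10 seeds.

What passing these tests shows: the optimizer finds the argmax of its
objective exactly, the objective estimates its population counterpart
consistently, and asymmetric intervals dominate symmetric ones when the
zero anchor is in the grid. What it does not show: real classifier scores
are not Beta-distributed, are often miscalibrated, and are correlated with
their labels through a trained model rather than by construction — so
performance numbers on synthetic mixtures do not transfer to any particular
dataset, only the structural guarantees do.

`simulate_features()` provides Gaussian two-class feature tables for
exercising the full pipeline; `downsample_balanced()` implements the
balanced scenario by keeping the whole minority class and a seeded uniform
subsample of the majority class of equal size, applied to the dataset
before splitting.

## The experiment pipeline

`run_experiment()` mirrors a standard evaluation: stratified hold-out split
(per-class proportions preserved to one sample; presets 0.4 and 0.5 for
the training share), a pluggable probabilistic base classifier (default:
logistic regression via `glm`; anything with `fit(x, y)` and
`prob(model, x)` returning probabilities plugs in — the optimizers never
look at the model, only at scores), then three rows: no abstention, best
symmetric interval, best asymmetric interval.

One design point is deliberate and flagged: by default the interval is
selected on the same held-out scores it is reported on, which matches the
common practice of tuning the operating point on the test set but biases
the reported MCC upward. For unbiased reporting set
`experiment_config(select_fraction = ...)` to carve a selection set out of
the held-out data; intervals are then chosen on the selection set and all
reported numbers come from the untouched remainder.

Rejected fractions are reported exactly; `format_report(band_rejected =
TRUE)` renders them as "< k%" bands for display only.

## Problem sizes used in the checks

The bundled suites run the optimizer-vs-brute-force comparison on 20 score
sets of $n = 200$, the monotonicity and nesting properties on 100 instances,
MCC algebra on 1,000 random confusion tables, parameter recovery on 10
samples of $n = 10{,}000$, and the imbalanced-improvement check on 20
samples of $n = 1{,}000$ — sizes at which the binomial noise is small
relative to the effects being asserted while the full suite stays fast.

## Limitations

* Scores are taken at face value; no calibration is applied or checked.
  Miscalibrated scores shift where the useful abstention region lies.
* The search is grid-based; the returned interval is optimal on the grid,
  not over the continuum (the objective being piecewise constant, a finer
  grid can only change the result at the resolution of adjacent scores).
* Binary classification only; no per-class rejection costs and no
  multi-class extension.
* A single split and a single selected interval: no cross-validation or
  averaging over repeated splits is built in.
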