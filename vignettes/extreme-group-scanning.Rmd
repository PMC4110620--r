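---
title: "Extreme-group logistic scanning of survival cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme-group logistic scanning of survival cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremeScan)
```

## The problem

Prognostic gene signatures derived from tumour expression profiles rarely
replicate between studies. Two recurring causes are (i) leaning on full
Kaplan-Meier survival curves built from heavily right-censored, imprecise
follow-up data, and (ii) mixing clinically heterogeneous cases so that stage
effects swamp the biology of interest. `extremeScan` implements an
alternative design: after stratifying the cohort on clinical criteria, only
the two *extremes* of the survival spectrum are compared — the k earliest
deaths against the k longest survivors, equal in size by construction and
selected purely by rank, never by an arbitrary time cut-off. Cases inside a
group are treated as exchangeable, so the design only asks of the follow-up
data that the extremes be identifiable; a censored record with long
follow-up still certifies long survival because its observed time is a lower
bound.

## Per-gene model and the pair-counting AUC

For each gene, class membership (1 = early event, 0 = long survivor) is
modelled by univariable logistic regression on the gene's log expression.
The accuracy of a gene is the area under its ROC curve, computed by the
pair-counting identity: over all cross-class value pairs, count pairs in the
dominant direction (1 credit) and ties (1/2 credit) and divide by the number
of pairs. This equals the Mann-Whitney U statistic scaled by `n1*n0`, and —
because fitted logistic probabilities are monotone in the covariate — the
AUC of the model's predictions. For example, if 320 of the 400 pairs between
two 20-case groups favour one class, the accuracy is 0.8; values of 0.8 or
more are conventionally read as excellent discrimination.

Two conventions matter and are documented choices:

* **Folding.** The pair comparison is directionless, so the reported
  accuracy is `max(a, 1 - a) >= 0.5`. The directional value and the slope
  sign are retained alongside (`aucDirectional`, `slope`) so risk genes can
  be told from protective genes.
* **Ties** receive half credit, the standard Mann-Whitney treatment.

Significance of the slope uses the likelihood-ratio (chi-square "ANOVA")
test: twice the log-likelihood gain of the one-covariate model over the
intercept-only model, referred to chi-square with 1 df. Because 20-vs-20
comparisons frequently separate perfectly, separation is detected and the
coefficients are reported *capped* at a documented bound
(`|slope| * sd(x) = 30`, with the intercept placing the decision boundary at
the midpoint of the inter-class gap); the rank-based AUC is unaffected and
the LRT is evaluated at the capped coefficients, keeping every p-value
finite and in (0, 1].

## Window resampling

To guard against the arbitrariness of one particular group of 20, the
extreme groups are extended to m = 40 ordered cases each and resampled:

* `sequentialWindows(group, k)`: the m − k + 1 consecutive rank windows
  (1–20, 2–21, …, 21–40 for m = 40, k = 20). Middle cases are
  over-represented.
* `revolvingWindows(group, k)`: m wrap-around windows; every case appears
  in exactly k of them, removing the uneven sampling while preserving rank
  order as far as possible.
* `bootstrapWindows(group, k, B, seed)`: B random k-subsets, for cohorts
  whose survival times are too imprecise to trust ranks.

Each moving window is compared against the fixed opposing core, and a gene
scores a *hit* when its folded AUC exceeds a threshold (default 0.8, strict
inequality). The bidirectional design — 40 early-side windows against the
fixed 20 longest survivors plus 40 late-side windows against the fixed 20
earliest deaths — gives each gene 80 opportunities; `rankGenes` sorts by hit
count (ties: mean AUC, then gene id). `allPairsScan` instead crosses every
early window with every late window (30 × 30 = 900 comparisons), yielding a
full per-gene AUC distribution that `ksCompare` can test against a
background set (e.g. keyword-flagged immune genes versus all genes).

A note on the sequential design: for m = 40, k = 20 the enumeration
1–20 … 21–40 contains 21 windows (m − k + 1), which is what
`sequentialWindows` produces.

The scan computes hit counts from the folded AUC of the raw window values
rather than refitting a logistic model per window: the two are identical
because the model's score is a strictly monotone transform of the single
covariate (asserted as a property test), and the shortcut turns a
10^4-gene × 80-window scan into seconds of rank arithmetic. Model-based
quantities (slope, LRT p) are produced where they are actually consumed —
the initial core-group table and the validation stages.

## Validation

* **Leave-one-out** (`leaveOneOut`): for each gene and each of the n cases,
  refit on n − 1 and classify the held-out case at probability 0.5. Row
  means are per-gene LOO accuracies; column means are per-case consensus
  values that expose outlier cases mispredicted by most genes.
  `clusterPredictionPatterns` orders genes by average-linkage hierarchical
  clustering of the correctness rows under Hamming distance (the distance
  and linkage are this package's choice).
* **Split-half** (`splitHalf`): within each class the ordered cases are
  split into odd- and even-ranked halves; the straight and crossed
  half-pairings, each evaluated in both directions, give four held-out AUCs
  per gene. As above, the held-out folded AUC is computed directly from the
  held-out values (monotone-score identity; the unit suite verifies the
  equality against explicit glm refits).
* **Anchor correlations** (`geneCorrelations`): Pearson correlation of a
  top gene against the other candidates over the analysis cases, with
  counts above 0.7/0.8 — highly correlated genes are not independent
  predictors.

## The Kaplan-Meier baseline

`kmQuantileTest` is the conventional comparator: all joined cases are split
into q near-equal expression quantiles (default q = 4; rank-based
assignment, ties broken by stable sample order) and equality of the
survival curves is tested by the log-rank (Mantel-Cox) chi-square on
q − 1 df. The source material for this design names only "a chi square
test of equality between quantiles"; log-rank is the conventional reading
and is stated here as an interpretation. The estimator and test are
delegated to the `survival` package; the unit suite pins them to
hand-computed product-limit and observed-minus-expected tables.
`compareMethods` reports the overlap between the logistic and KM rankings
at chosen depths.

## The synthetic cohort generator

`generateCohort(SyntheticSpec(...))` produces the structure the method
assumes, with complete ground truth, so every stage can be tested without
any external download:

* **Survival**: two latent classes with exponential times and an enforced
  gap — early events die within 24 months (event observed), survivors live
  beyond 72 months with a configurable fraction right-censored uniformly
  over follow-up. Only ordering and class membership matter to the method,
  so this minimal model suffices.
* **Expression**: log2-scale baseline 7, residual sd 1. A block of signal
  genes shares a per-case latent factor and is shifted `effectDelta`
  noise-sd units higher in survivors. `signalBlockRho` is the *marginal*
  Pearson correlation target among signal genes across the cohort (that is
  what an observed correlation matrix measures); the residual factor
  loading is solved from `rho` and `delta`, and combinations where the
  class shift alone forces a higher correlation than requested are refused
  as infeasible.
* **Outliers**: `outlierFlipCount` cases have their expression-class
  linkage inverted while keeping labels and times — these should surface
  as majority-mispredicted columns of the LOO matrix.
* **Contamination**: optional stage-III-like cases with short survival
  whose signal-gene expression sits at *survivor* level — modelling
  advanced disease in which the protective signal no longer determines
  outcome — plus a disjoint marker-gene block elevated only in them. In an
  all-case KM analysis these marker genes and the broken signal
  association reproduce the qualitative failure mode that motivates
  stratification: the stage I/II extreme-group scan recovers the planted
  signal while the unstratified KM ranking partially misses it.

Defaults (100 cases, 2000 genes, 20 signal genes, delta 2.5, rho 0.75,
censor rate 0.5) were fixed once to mirror the cohort scale the method
targets. What the generator does **not** emulate: probe-level artefacts,
batch effects, non-Gaussian expression tails, intermediate-survival cases,
or competing risks — so a passing recovery test demonstrates internal
consistency of the machinery, not performance on real microarray data.

## Numerical and policy choices

* Quartiles in `filterVariableGenes` use linear interpolation
  (`type = 7`); the floor criterion (fraction of values above 6.6 logs)
  applies only on the raw log scale and is disabled for standard scores.
  Both filter cut-offs are free parameters because the log base of any
  particular upstream data set is not knowable from the matrix alone.
* Probe collapsing averages log-scale values arithmetically; unmapped
  probes are dropped and counted, never silently.
* Column standardisation (`scaleArrays`) uses the n − 1 standard
  deviation and refuses zero-variance samples by name.
* Extreme-group ties on survival time break by event-before-censored, then
  stable input order; selection is fully deterministic.
* Classification threshold is fitted probability 0.5 throughout.
* One root seed drives each pipeline run; the bootstrap window generator
  derives per-side seeds from it.

## Problem sizes used by the test suite

The packaged tests exercise the full pipeline at the method's native scale
— 2000-gene, 100-case cohorts with 20-vs-20 cores and 40-case extended
groups (80-comparison bidirectional scans), 500-instance oracle batteries
for the AUC, and 25 numerically maximised likelihood comparisons — sizes
chosen to match the design the package targets while keeping a complete
run in the low minutes on one core.

## Known limitations

* Univariable models only: no multivariable or penalised signatures are
  constructed, by design.
* The LRT p-value is asymptotic; at n = 40 its small-sample behaviour is
  checked empirically (type-I fraction near 0.05) but not exact.
* With thousands of null genes, a handful will reach chance AUCs near 0.8
  on any fixed 40+40 extreme selection, and because windows share most of
  their membership such genes accumulate correlated window hits; hit-count
  screens therefore control gene-level stability, not family-wise error.
* GEO ingestion is limited to series-matrix-style delimited text plus an
  optional probe map; CEL-level processing is out of scope.
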