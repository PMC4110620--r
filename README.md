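# extremeScan

Prognostic-gene discovery from the extremes of a right-censored survival
cohort, for transcriptomics analysts who have a log-scale expression matrix
(microarray series-matrix-style text or anything similar) and a clinical
table with survival or recurrence follow-up.

Instead of fitting Kaplan-Meier curves to a whole, heavily censored cohort,
the package stratifies cases on clinical criteria, selects the k earliest
deaths and the k longest survivors (equal-sized groups, chosen purely by
rank), and asks of every gene how well it separates the two classes under a
univariable logistic model. A gene's accuracy is the concordance area under
its ROC curve, computed by pair counting: over all n1·n0 cross-class value
pairs,

    AUC = (#{x1 > x0} + ½·#{x1 = x0}) / (n1·n0) = U / (n1·n0),

the normalized Mann-Whitney U statistic (320 favourable pairs out of 400
between two 20-case groups ⇒ AUC = 0.8). Slope significance is the
likelihood-ratio chi-square 2(ℓ_full − ℓ_null) on 1 df. Gene lists are then
stabilised by resampling the extended extreme groups (m = 40 per side) with
sequential, revolving (wrap-around, each case sampled exactly k times) or
all-pairs window families, counting per-gene windows with AUC > 0.8, and
validated by leave-one-out and alternating split-half schemes. An
expression-quantile Kaplan-Meier log-rank baseline provides the
conventional comparison, and a seeded synthetic-cohort generator with
planted signal genes supplies ground truth for every stage.

## Worked example

```r
library(extremeScan)

# the pair-counting identity on the 20-vs-20 worked example
pairwiseAUC(rep(16.5, 20), 1:20)
#> [1] 0.8

# a synthetic cohort: 100 cases, 500 genes, 10 planted signal genes
# (delta 2.5 sd, block correlation 0.75, survivors censored at rate 0.5)
syn <- generateCohort(SyntheticSpec(nCases = 100, nGenes = 500,
                                    nSignalGenes = 10, seed = 42))
res <- runPipeline(list(
  input      = list(expression = syn$expression, cohort = syn$cohort),
  scan       = list(mode = "revolving", threshold = 0.8, minHits = 20),
  validation = list(topGenes = 10),
  km         = list(q = 4, topN = 20),
  seed       = 42))

res$log$initial_scan$countAboveThreshold   # genes with core 20-vs-20 AUC >= 0.8
#> [1] 10
head(res$ranking[, c("gene", "hits", "total", "meanAUC")])
#>       gene hits total  meanAUC
#> 1 gene0009   80    80 0.991875
#> 2 gene0006   80    80 0.989375
#> 3 gene0003   80    80 0.988750
#> 4 gene0007   80    80 0.981250
#> 5 gene0001   80    80 0.977500
#> 6 gene0002   80    80 0.971875
mean(res$validation$looAccuracy)           # leave-one-out accuracy, top genes
#> [1] 0.9075
res$comparison$overlapCount                # overlap with the KM top-20
#> [1] 11
```

Reading: all ten planted signal genes (`gene0001` … `gene0010`) reach the
core-comparison AUC ≥ 0.8 and fill the top of the 80-comparison revolving
window ranking with perfect hit counts; their leave-one-out accuracy
averages 0.9075, and 11 of them also appear in the conventional KM quantile
top-20 — the two methods agree on the strongest genes while the scan ranks
them more completely.

File-based runs use the same machinery (`readExpression` +
`readClinical` with a column-name schema, or the thin wrapper at
`inst/scripts/extremescan.R` with `simulate` / `run` subcommands and a
JSON/YAML config).

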