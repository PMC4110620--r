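test_that("generation is deterministic given the seed and seed-sensitive otherwise", {
  a <- generateCohort(SyntheticSpec(nCases = 30, nGenes = 40, nSignalGenes = 4,
                                    seed = 99))
  b <- generateCohort(SyntheticSpec(nCases = 30, nGenes = 40, nSignalGenes = 4,
                                    seed = 99))
  c <- generateCohort(SyntheticSpec(nCases = 30, nGenes = 40, nSignalGenes = 4,
                                    seed = 100))
  expect_identical(exprValues(a$expression), exprValues(b$expression))
  expect_identical(cohortData(a$cohort), cohortData(b$cohort))
  expect_false(identical(exprValues(a$expression), exprValues(c$expression)))
})

test_that("the cohort has the promised survival structure", {
  spec <- SyntheticSpec(nCases = 60, nGenes = 20, nSignalGenes = 2,
                        censorRate = 0.4, seed = 7)
  syn <- generateCohort(spec)
  d <- cohortData(syn$cohort)
  cls <- syn$truth$class
  early <- d[cls[d$sample_id] == "early", ]
  late <- d[cls[d$sample_id] == "late", ]
  expect_true(all(early$event))
  expect_true(all(early$time < 24))
  expect_true(all(late$time > 72))          # enforced class gap
  expect_gt(sum(!late$event), 0)            # censoring confined to survivors
  frac <- mean(!late$event)
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / nrow(late)))
})

test_that("signal genes carry the requested shift and marginal correlation", {
  spec <- SyntheticSpec(nCases = 300, nGenes = 60, nSignalGenes = 10,
                        effectDelta = 2.5, signalBlockRho = 0.75, seed = 31)
  syn <- generateCohort(spec)
  v <- exprValues(syn$expression)
  cls <- syn$truth$class
  eIds <- names(cls)[cls == "early"]; lIds <- names(cls)[cls == "late"]
  shifts <- rowMeans(v[syn$truth$signalGenes, lIds]) -
    rowMeans(v[syn$truth$signalGenes, eIds])
  se <- sqrt(1 / length(eIds) + 1 / length(lIds))   # noiseSd = 1
  expect_true(all(abs(shifts - 2.5) < 3 * se))
  cm <- cor(t(v[syn$truth$signalGenes, ]))
  offDiag <- cm[upper.tri(cm)]
  expect_lt(abs(mean(offDiag) - 0.75), 0.05)
  # noise genes uncorrelated with the block on average
  noise <- setdiff(rownames(v), syn$truth$signalGenes)[1:10]
  cross <- cor(t(v[c(syn$truth$signalGenes[1], noise), ]))[1, -1]
  expect_lt(max(abs(cross)), 0.35)
})

test_that("infeasible correlation targets and invalid specs are refused", {
  expect_error(generateCohort(SyntheticSpec(effectDelta = 6, signalBlockRho = 0.5)),
               "infeasible correlation")
  expect_error(SyntheticSpec(signalBlockRho = 1), "lie in")
  expect_error(SyntheticSpec(nSignalGenes = 30, nGenes = 20), "exceed")
  expect_error(SyntheticSpec(censorRate = 1.2), "censorRate")
})

test_that("outlier flips invert the expression-class linkage of chosen cases", {
  spec <- SyntheticSpec(nCases = 40, nGenes = 30, nSignalGenes = 6,
                        effectDelta = 3, outlierFlipCount = 4, seed = 55)
  syn <- generateCohort(spec)
  expect_length(syn$truth$outliers, 4L)
  v <- exprValues(syn$expression)
  cls <- syn$truth$class
  sigMeans <- colMeans(v[syn$truth$signalGenes, ])
  mid <- mean(sigMeans)
  for (id in syn$truth$outliers) {
    # an outlier's signal expression sits on the wrong side of the midpoint
    if (cls[[id]] == "early") expect_gt(sigMeans[[id]], mid)
    else expect_lt(sigMeans[[id]], mid)
  }
})

test_that("the contamination block is confined to stage III cases", {
  spec <- SyntheticSpec(nCases = 40, nGenes = 50, nSignalGenes = 5,
                        nContamCases = 10, nContamGenes = 5, contamDelta = 3,
                        seed = 77)
  syn <- generateCohort(spec)
  d <- cohortData(syn$cohort)
  cls <- syn$truth$class
  expect_equal(sum(cls == "contam"), 10L)
  expect_true(all(d$stage[cls[d$sample_id] == "contam"] == "III"))
  expect_true(all(d$stage[cls[d$sample_id] != "contam"] %in% c("I", "II")))
  v <- exprValues(syn$expression)
  contamIds <- names(cls)[cls == "contam"]
  coreIds <- names(cls)[cls != "contam"]
  lift <- rowMeans(v[syn$truth$contamGenes, contamIds]) -
    rowMeans(v[syn$truth$contamGenes, coreIds])
  expect_true(all(lift > 1.5))
  # contaminated cases express signal genes at survivor level, not early level
  cls2 <- cls[cls != "contam"]
  lateIds <- names(cls2)[cls2 == "late"]; earlyIds <- names(cls2)[cls2 == "early"]
  sigContam <- mean(v[syn$truth$signalGenes, contamIds])
  expect_lt(abs(sigContam - mean(v[syn$truth$signalGenes, lateIds])), 0.5)
  expect_gt(sigContam - mean(v[syn$truth$signalGenes, earlyIds]), 1)
})

test_that("written cohorts read back identically through the package readers", {
  syn <- generateCohort(SyntheticSpec(nCases = 20, nGenes = 10,
                                      nSignalGenes = 2, seed = 3))
  dir <- tempfile()
  paths <- writeCohort(syn, dir)
  expr <- readExpression(paths[["expression"]])
  expect_equal(exprValues(expr), exprValues(syn$expression), tolerance = 1e-12)
  co <- readClinical(paths[["clinical"]],
                     schema = list(id = "sample_id", time = "time",
                                   event = "event", stage = "stage",
                                   adjuvant = "adjuvant"),
                     expression = expr)
  expect_equal(cohortData(co)$time, cohortData(syn$cohort)$time,
               tolerance = 1e-12)
  expect_equal(cohortData(co)$event, cohortData(syn$cohort)$event)
  expect_length(joinReport(co)$unmatchedClinical, 0L)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$signalGenes, syn$truth$signalGenes)
})
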