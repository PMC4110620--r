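test_that("sequential windows enumerate all m - k + 1 consecutive rank windows", {
  grp <- sprintf("c%02d", 1:40)
  ws <- sequentialWindows(grp, 20)
  expect_length(windows(ws), 21L)
  expect_equal(windows(ws)[[1]], grp[1:20])
  expect_equal(windows(ws)[[21]], grp[21:40])
  # m = k: a single window, the whole group
  one <- sequentialWindows(grp[1:5], 5)
  expect_length(windows(one), 1L)
  expect_equal(windows(one)[[1]], grp[1:5])
  # m = 5, k = 2 enumeration
  small <- sequentialWindows(letters[1:5], 2)
  expect_equal(windows(small),
               list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e")))
  expect_error(sequentialWindows(letters[1:3], 4), "exceeds")
})

test_that("revolving windows wrap around so each case is sampled exactly k times", {
  grp <- sprintf("c%02d", 1:40)
  ws <- revolvingWindows(grp, 20)
  expect_length(windows(ws), 40L)
  counts <- table(unlist(windows(ws)))
  expect_true(all(counts == 20))
  # m = 5, k = 3: window 4 wraps to rank 1, window 5 to ranks 1-2
  small <- revolvingWindows(letters[1:5], 3)
  expect_equal(windows(small)[[4]], c("d", "e", "a"))
  expect_equal(windows(small)[[5]], c("e", "a", "b"))
  expect_true(all(table(unlist(windows(small))) == 3))
  # m = k: m rotations of the full group
  rot <- revolvingWindows(letters[1:4], 4)
  expect_length(windows(rot), 4L)
  expect_true(all(vapply(windows(rot), setequal, TRUE, letters[1:4])))
  expect_error(revolvingWindows(letters[1:3], 4), "exceeds")
})

test_that("revolving coverage and window counts hold for all k <= m up to m = 20", {
  for (m in c(3, 7, 12, 20)) {
    grp <- paste0("x", seq_len(m))
    for (k in seq_len(m)) {
      rev <- revolvingWindows(grp, k)
      expect_length(windows(rev), m)
      expect_true(all(table(unlist(windows(rev))) == k))
      expect_length(windows(sequentialWindows(grp, k)), m - k + 1L)
    }
  }
})

test_that("scanWindows counts threshold hits and refuses overlapping membership", {
  syn <- generateCohort(SyntheticSpec(nCases = 40, nGenes = 30,
                                      nSignalGenes = 3, effectDelta = 3,
                                      seed = 5))
  g <- selectExtremes(syn$cohort, SelectionCriteria(coreSize = 5,
                                                    extendedSize = 15))
  ew <- revolvingWindows(earlyGroup(g, TRUE), 5, "early")
  sc <- scanWindows(syn$expression, ew, lateGroup(g), threshold = 0.8)
  expect_equal(unique(sc$total), 15L)
  expect_true(all(sc$hits >= 0 & sc$hits <= sc$total))
  # planted signal genes hit nearly every window; a constant gene never hits
  sig <- sc$hits[sc$gene %in% syn$truth$signalGenes]
  expect_true(all(sig >= 13))
  v <- exprValues(syn$expression); v["gene0030", ] <- 7
  flat <- scanWindows(ExpressionMatrix(v), ew, lateGroup(g))
  expect_equal(flat$hits[flat$gene == "gene0030"], 0)
  # membership overlap with the fixed group errors
  expect_error(scanWindows(syn$expression, ew, earlyGroup(g)), "overlap")
})

test_that("scan hit counts are invariant to gene and window order", {
  syn <- generateCohort(SyntheticSpec(nCases = 30, nGenes = 12,
                                      nSignalGenes = 2, seed = 8))
  g <- selectExtremes(syn$cohort, SelectionCriteria(coreSize = 4,
                                                    extendedSize = 10))
  ws <- revolvingWindows(earlyGroup(g, TRUE), 4, "early")
  base <- scanWindows(syn$expression, ws, lateGroup(g))
  set.seed(1)
  shuffled <- new("WindowSet", windows = sample(windows(ws)),
                  kind = "revolving", sourceGroup = "early",
                  windowSize = 4L, sourceSize = 10L)
  reGene <- scanWindows(syn$expression, shuffled, lateGroup(g),
                        genes = sample(geneIds(syn$expression)))
  expect_equal(reGene$hits[match(base$gene, reGene$gene)], base$hits)
})

test_that("the bidirectional design totals 80 comparisons and allpairs |E|*|L|", {
  syn <- generateCohort(SyntheticSpec(nCases = 100, nGenes = 15,
                                      nSignalGenes = 2, seed = 3))
  g <- selectExtremes(syn$cohort, SelectionCriteria())
  ew <- revolvingWindows(earlyGroup(g, TRUE), 20, "early")
  lw <- revolvingWindows(lateGroup(g, TRUE), 20, "late")
  both <- combineScores(
    scanWindows(syn$expression, ew, lateGroup(g)),
    scanWindows(syn$expression, lw, earlyGroup(g)))
  expect_equal(unique(both$total), 80L)
  expect_equal(both$hits, both$hits1 + both$hits2)

  # all-pairs on 3 x 4 windows equals one-at-a-time recomputation
  e3 <- new("WindowSet", windows = windows(ew)[1:3], kind = "bootstrap",
            sourceGroup = "early", windowSize = 20L, sourceSize = 40L)
  l4 <- new("WindowSet", windows = windows(lw)[1:4], kind = "bootstrap",
            sourceGroup = "late", windowSize = 20L, sourceSize = 40L)
  ap <- allPairsScan(syn$expression, e3, l4, genes = geneIds(syn$expression)[1:5])
  expect_equal(unique(ap$total), 12L)
  aucs <- attr(ap, "auc")
  v <- exprValues(syn$expression)
  i <- 0
  for (wl in windows(l4)) for (we in windows(e3)) {
    i <- i + 1
    for (gi in 1:5)
      expect_equal(unname(aucs[gi, i]),
                   pairwiseAUC(v[gi, we], v[gi, wl]))
  }
  expect_error(allPairsScan(syn$expression, e3, e3), "overlap")
})

test_that("rankGenes filters on hit count and orders hits, mean AUC, id", {
  sc <- data.frame(gene = c("a", "b", "c", "d"),
                   hits = c(50, 20, 19, 0), total = 80,
                   meanAUC = c(0.9, 0.82, 0.8, 0.5))
  expect_equal(rankGenes(sc, minHits = 20)$gene, c("a", "b"))
  expect_equal(rankGenes(sc, minHits = 81)$gene, character(0))
  expect_equal(rankGenes(sc, minHits = 0)$gene, c("a", "b", "c", "d"))
  tie <- data.frame(gene = c("z", "y"), hits = c(10, 10), total = 40,
                    meanAUC = c(0.7, 0.7))
  expect_equal(rankGenes(tie)$gene, c("y", "z"))
  sc$total <- c(80, 80, 40, 80)
  expect_error(rankGenes(sc), "common total")
})
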