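test_that("probe collapsing averages per gene, drops unmapped probes, and is idempotent", {
  # two probes for one gene: arithmetic mean per sample
  v <- rbind(p1 = c(4, 6), p2 = c(6, 8), p3 = c(1, 2))
  colnames(v) <- c("sA", "sB")
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("G", "G", "H"))
  out <- collapseProbes(v, map)
  expect_equal(out$values["G", ], c(sA = 5, sB = 7))
  expect_equal(out$values["H", ], c(sA = 1, sB = 2))

  # 5 probes -> 3 genes, means checked against independent per-gene tally
  set.seed(11)
  v5 <- matrix(round(rnorm(20, 7), 3), 5, 4,
               dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  map5 <- data.frame(probe = paste0("p", 1:5),
                     gene = c("A", "A", "B", "C", "C"))
  out5 <- collapseProbes(v5, map5)
  expect_equal(nrow(out5$values), 3L)
  for (g in c("A", "B", "C")) {
    rows <- map5$probe[map5$gene == g]
    expected <- colSums(v5[rows, , drop = FALSE]) / length(rows)
    expect_equal(out5$values[g, ], expected)
  }

  # unmapped probes are dropped and counted
  mapDrop <- map5[1:4, ]
  outDrop <- collapseProbes(v5, mapDrop)
  expect_equal(outDrop$report$nDroppedProbes, 1L)
  expect_equal(outDrop$report$droppedProbes, "p5")

  # collapsing an already-collapsed matrix is the identity
  idMap <- data.frame(probe = rownames(out5$values), gene = rownames(out5$values))
  again <- collapseProbes(out5$values, idMap)
  expect_equal(again$values, out5$values)
})

test_that("readExpression parses delimited tables and reports errors by row/column", {
  tsv <- tempfile(fileext = ".tsv")
  m <- matrix(c(4, 6, 1, 6, 8, 2), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("sA", "sB")))
  writeLines(c("gene_id\tsA\tsB",
               paste("g1", 4, 6, sep = "\t"),
               paste("g2", 6, 8, sep = "\t"),
               paste("g3", 1, 2, sep = "\t")), tsv)
  x <- readExpression(tsv)
  expect_s4_class(x, "ExpressionMatrix")
  expect_equal(exprValues(x), m)
  expect_identical(scaleTag(x), "raw_log")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA\tsB", "g1\t4\toops"), bad)
  err <- tryCatch(readExpression(bad), error = conditionMessage)
  expect_match(err, "g1")
  expect_match(err, "sB")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA\tsA", "g1\t4\t5"), dup)
  expect_error(readExpression(dup), "duplicate sample ids")
})

test_that("expression round-trips through write/read to 1e-12", {
  set.seed(3)
  v <- matrix(rnorm(40, 7, 2), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  x <- ExpressionMatrix(v)
  p <- tempfile(fileext = ".tsv")
  writeExpression(x, p)
  y <- readExpression(p)
  expect_equal(exprValues(y), v, tolerance = 1e-12)
})

test_that("scaleArrays standardises each sample column with the n-1 sd", {
  x <- ExpressionMatrix(matrix(c(1, 2, 3, 5, 5, 8), 3, 2,
                               dimnames = list(paste0("g", 1:3), c("a", "b"))))
  s <- scaleArrays(x)
  expect_identical(scaleTag(s), "standard_score")
  expect_equal(exprValues(s)[, "a"], c(g1 = -1, g2 = 0, g3 = 1))

  # random fixture matches brute-force per-column computation
  set.seed(5)
  v <- matrix(rnorm(60, 7), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sc <- exprValues(scaleArrays(ExpressionMatrix(v)))
  for (j in seq_len(ncol(v))) {
    mu <- sum(v[, j]) / nrow(v)
    sdj <- sqrt(sum((v[, j] - mu)^2) / (nrow(v) - 1))
    expect_equal(sc[, j], (v[, j] - mu) / sdj)
    expect_lt(abs(mean(sc[, j])), 1e-9)
    expect_lt(abs(sd(sc[, j]) - 1), 1e-9)
  }

  # affine invariance: scale(a*x + b) == scale(x) for a > 0
  v2 <- v; v2[, 2] <- 3.7 * v[, 2] + 11
  expect_equal(exprValues(scaleArrays(ExpressionMatrix(v2)))[, 2], sc[, 2])

  # zero-variance column errors naming the sample
  v3 <- v; v3[, 4] <- 6.6
  expect_error(scaleArrays(ExpressionMatrix(v3)), "s4")
  # double scaling is refused
  expect_error(scaleArrays(scaleArrays(ExpressionMatrix(v))), "raw_log")
})

test_that("readClinical joins to expression and reports unmatched ids", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,months,status,tnm",
               "s1,12.5,dead,1",
               "s2,80,alive,2",
               "s3,45,0,IIIA"), csv)
  expr <- ExpressionMatrix(matrix(rnorm(6, 7), 2, 3,
    dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
  co <- readClinical(csv, schema = list(id = "id", time = "months",
                                        event = "status", stage = "tnm"),
                     expression = expr)
  d <- cohortData(co)
  expect_equal(d$event, c(TRUE, FALSE, FALSE))
  expect_equal(as.character(d$stage), c("I", "II", "III"))
  expect_equal(length(joinReport(co)$matched), 3L)
  expect_equal(length(joinReport(co)$unmatchedClinical), 0L)

  # one id absent from expression is reported, not dropped
  expr2 <- expr[, c("s1", "s2")]
  co2 <- readClinical(csv, schema = list(id = "id", time = "months",
                                         event = "status"),
                      expression = expr2)
  expect_equal(joinReport(co2)$unmatchedClinical, "s3")
  expect_equal(nrow(cohortData(co2)), 3L)

  # schema and record-level errors
  expect_error(readClinical(csv, schema = list(id = "id", time = "nope",
                                               event = "status")),
               "schema error")
  neg <- tempfile(fileext = ".csv")
  writeLines(c("id,months,status", "s1,-3,dead"), neg)
  expect_error(readClinical(neg, schema = list(id = "id", time = "months",
                                               event = "status")),
               "negative or missing")
})

test_that("keyword flagging matches descriptions case-insensitively and unions extra genes", {
  ann <- data.frame(
    gene_id = c("BLNK", "CD79A", "KRT7", "VEGFA", "BANK1", "CD3E",
                "MXI1", "GM2A", "DTNB", "LAX1"),
    description = c("B-cell linker", "B-CELL antigen receptor subunit",
                    "keratin 7", "vascular growth factor",
                    "B cell scaffold", "T-cell surface glycoprotein",
                    "MAX interactor", "ganglioside activator",
                    "dystrobrevin beta", "lymphocyte transmembrane adaptor"))
  hits <- flagGenesByKeyword(ann, keywords = "B-cell")
  expect_setequal(hits, c("BLNK", "CD79A"))
  # two keyword hits + one extra gene restricted to the universe
  out <- flagGenesByKeyword(ann, keywords = c("B-cell"),
                            extraGenes = c("MXI1", "NOT_PRESENT"))
  expect_setequal(out, c("BLNK", "CD79A", "MXI1"))
  # duplicate gene_ids concatenate descriptions
  ann2 <- rbind(ann, data.frame(gene_id = "KRT7", description = "lymph node"))
  expect_true("KRT7" %in% flagGenesByKeyword(ann2, "lymph"))
  # empty keyword list after trimming is refused
  expect_error(flagGenesByKeyword(ann, keywords = c("", "  ")), "non-empty")
})
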