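#' Leave-one-out validation of per-gene logistic models
#'
#' For each gene and each case, a logistic model is fitted on the remaining
#' n - 1 cases and the held-out case is classified at fitted probability
#' 0.5; the matrix records whether each prediction was correct. Row means
#' are per-gene LOO accuracies, column means per-case prediction consensus
#' (cases mispredicted by most genes stand out as outliers).
#'
#' Folds with perfect separation are classified by the same capped-model
#' rule as [fitGeneModel()] (the decision boundary sits mid-gap).
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param cases labelled case set from [labelledCases()] (two non-empty
#'   classes; typically 20 + 20).
#' @param genes gene ids to validate (default all).
#' @return Logical matrix (genes x cases, dimnames set), TRUE = predicted
#'   correctly.
#' @export
leaveOneOut <- function(m, cases, genes = geneIds(m)) {
  stopifnot(is(m, "ExpressionMatrix"))
  v <- exprValues(m)[genes, cases$sample_id, drop = FALSE]
  y <- cases$label
  n <- length(y)
  if (sum(y) < 2L || sum(1L - y) < 2L)
    stop("each class needs at least 2 cases so no fold empties a class")
  out <- matrix(NA, length(genes), n,
                dimnames = list(genes, cases$sample_id))
  for (g in seq_along(genes)) {
    x <- v[g, ]
    for (i in seq_len(n)) {
      fit <- fitGeneModel(x[-i], y[-i])
      pred <- as.integer(fit$intercept + fit$slope * x[i] > 0)
      out[g, i] <- pred == y[i]
    }
  }
  out
}

#' Per-gene and per-case summaries of a LOO matrix
#'
#' @param loo logical matrix from [leaveOneOut()].
#' @return \code{looAccuracy}: named numeric vector of per-gene accuracies
#'   (row means); \code{caseConsensus}: named numeric vector of per-case
#'   fractions of genes predicting the case correctly (column means).
#' @export
looAccuracy <- function(loo) rowMeans(loo)

#' @rdname looAccuracy
#' @export
caseConsensus <- function(loo) colMeans(loo)

#' Alternating split-half validation
#'
#' Within each class the cases, in their survival-rank order, are split
#' into odd-indexed (A) and even-indexed (B) halves. Models are trained on
#' one half-pair and evaluated on the complementary one: the straight
#' pairing (A1+A0 vs B1+B0) and the crossed pairing (A1+B0 vs B1+A0), each
#' in both directions, give four held-out folded-AUC evaluations per gene,
#' whose mean is returned. Because the single-covariate model's score is
#' monotone in expression, the held-out folded AUC equals the folded AUC of
#' the held-out raw values, which is how it is computed.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param cases labelled case set with even class sizes, ordered by
#'   survival rank within class.
#' @param genes gene ids (default all).
#' @return data.frame: gene, meanHeldOutAUC, plus the four per-pairing AUCs
#'   (auc1..auc4).
#' @export
splitHalf <- function(m, cases, genes = geneIds(m)) {
  stopifnot(is(m, "ExpressionMatrix"))
  id1 <- cases$sample_id[cases$label == 1L]
  id0 <- cases$sample_id[cases$label == 0L]
  if (length(id1) %% 2L || length(id0) %% 2L)
    stop(sprintf("odd class size (class 1: %d, class 0: %d); both must be even",
                 length(id1), length(id0)))
  odd <- function(ids) ids[seq_along(ids) %% 2L == 1L]
  even <- function(ids) ids[seq_along(ids) %% 2L == 0L]
  a1 <- odd(id1); b1 <- even(id1); a0 <- odd(id0); b0 <- even(id0)
  v <- exprValues(m)[genes, , drop = FALSE]
  evalAUC <- function(test1, test0)
    rowFoldedAUC(v[, test1, drop = FALSE], v[, test0, drop = FALSE])
  # train (a1,a0) -> test (b1,b0); reverse; then the crossed pairing
  aucs <- cbind(evalAUC(b1, b0), evalAUC(a1, a0),
                evalAUC(b1, a0), evalAUC(a1, b0))
  data.frame(gene = genes, meanHeldOutAUC = rowMeans(aucs),
             auc1 = aucs[, 1L], auc2 = aucs[, 2L],
             auc3 = aucs[, 3L], auc4 = aucs[, 4L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster genes by their case-prediction patterns
#'
#' Hierarchical clustering (average linkage) of LOO correctness rows under
#' Hamming distance, so genes making the same case-by-case predictions —
#' right or wrong — group together.
#'
#' @param loo logical matrix from [leaveOneOut()], >= 2 genes.
#' @param h optional cut height in Hamming-fraction units; \code{k} optional
#'   cluster count. When neither is given no cut is made.
#' @param k optional number of clusters for the cut.
#' @return list with \code{order} (gene ids in dendrogram leaf order),
#'   \code{hclust} (the stats::hclust tree) and \code{clusters} (named
#'   cluster assignments, NULL when no cut requested).
#' @export
clusterPredictionPatterns <- function(loo, h = NULL, k = NULL) {
  if (nrow(loo) < 2L) stop("need at least 2 genes to cluster")
  d <- stats::dist(loo * 1, method = "manhattan") / ncol(loo)  # Hamming fraction
  hc <- stats::hclust(d, method = "average")
  clusters <- NULL
  if (!is.null(h) || !is.null(k))
    clusters <- stats::cutree(hc, k = k, h = h)
  list(order = rownames(loo)[hc$order], hclust = hc, clusters = clusters)
}

#' Pearson correlation of an anchor gene with other genes
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param anchor gene id whose expression row is correlated against the
#'   others.
#' @param others gene ids to correlate (default: all other genes).
#' @param samples optional sample ids restricting the analysis cases.
#' @param thresholds correlation thresholds at which to count genes
#'   (default 0.7 and 0.8).
#' @return data.frame (gene, r) sorted by r descending;
#'   \code{attr(x, "counts")} holds the number of genes with r greater than
#'   each threshold.
#' @export
geneCorrelations <- function(m, anchor, others = NULL,
                             samples = sampleIds(m),
                             thresholds = c(0.7, 0.8)) {
  stopifnot(is(m, "ExpressionMatrix"), anchor %in% geneIds(m))
  if (length(samples) < 3L) stop("need at least 3 samples")
  others <- others %||% setdiff(geneIds(m), anchor)
  v <- exprValues(m)[, samples, drop = FALSE]
  r <- as.vector(stats::cor(v[anchor, ], t(v[others, , drop = FALSE])))
  out <- data.frame(gene = others, r = r, stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- stats::setNames(
    vapply(thresholds, function(t) sum(r > t), 1L),
    paste0("r>", thresholds))
  out
}
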