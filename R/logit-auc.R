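#' Concordance (ROC) area from all cross-class value pairs
#'
#' Every value of class 1 (early events) is compared with every value of
#' class 0 (long survivors): a pair in which the two values differ in the
#' dominant direction earns one credit, a tie half a credit, and the AUC is
#' total credit over the |x1|*|x0| pairs. This pair-counting ratio equals
#' the area under the ROC curve of the corresponding univariable logistic
#' model (the model's fitted probabilities are monotone in the covariate, so
#' ranks are preserved), and equals the Mann-Whitney U statistic divided by
#' |x1|*|x0|.
#'
#' The comparison is directionless: by default the value is folded so the
#' reported accuracy is \code{max(a, 1 - a) >= 0.5}. Use
#' \code{folded = FALSE} for the directional value
#' \eqn{P(X_1 > X_0) + 0.5 P(X_1 = X_0)}, which distinguishes risk genes
#' (high in early events) from protective genes.
#'
#' @param x1 numeric values of class 1 (early event group), non-empty.
#' @param x0 numeric values of class 0 (long survivor group), non-empty.
#' @param folded fold the result to be >= 0.5 (default TRUE).
#' @return AUC in [0, 1] ([0.5, 1] when folded).
#' @examples
#' pairwiseAUC(c(3, 4, 5), c(1, 2, 3.5))          # folded accuracy
#' pairwiseAUC(c(3, 4, 5), c(1, 2, 3.5), folded = FALSE)
#' @export
pairwiseAUC <- function(x1, x0, folded = TRUE) {
  if (length(x1) == 0L || length(x0) == 0L)
    stop("both classes must be non-empty")
  if (!all(is.finite(x1)) || !all(is.finite(x0)))
    stop("expression values must be finite")
  n1 <- length(x1); n0 <- length(x0)
  r <- rank(c(x1, x0), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n0)
  if (folded) max(a, 1 - a) else a
}

# Row-wise folded AUC for a genes x samples matrix split into two classes.
# Equivalent to apply(pairwiseAUC) per gene, vectorised over genes.
rowFoldedAUC <- function(v1, v0) {
  n1 <- ncol(v1); n0 <- ncol(v0)
  x <- cbind(v1, v0)
  r <- t(apply(x, 1L, rank, ties.method = "average"))
  if (nrow(x) == 1L) r <- matrix(r, nrow = 1L)
  u <- rowSums(r[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n0)
  pmax(a, 1 - a)
}

# Binomial log-likelihood of labels y in {0,1} under logit(p) = b0 + b1 x.
logLikLogistic <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Intercept-only maximised log-likelihood (closed form).
nullLogLik <- function(y) {
  n1 <- sum(y); n0 <- sum(1 - y); n <- n1 + n0
  ll <- 0
  if (n1 > 0) ll <- ll + n1 * log(n1 / n)
  if (n0 > 0) ll <- ll + n0 * log(n0 / n)
  ll
}

#' Likelihood-ratio (chi-square ANOVA) test of the logistic slope
#'
#' Tests whether a single-gene logistic model improves on the intercept-only
#' model: the statistic 2 (l_full - l_null) is referred to chi-square with
#' one degree of freedom.
#'
#' @param x numeric covariate (one gene's expression over the cases).
#' @param y binary labels (1 = early event, 0 = long survivor).
#' @param coefficients optional c(intercept, slope) at which to evaluate the
#'   full-model likelihood (used with capped coefficients under separation);
#'   by default the maximum-likelihood fit is used.
#' @return list with \code{statistic} (LR chi-square), \code{p} (upper-tail
#'   chi-square p-value, 1 df) and \code{logLikFull}, \code{logLikNull}.
#' @export
slopeLRT <- function(x, y, coefficients = NULL) {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  ll0 <- nullLogLik(y)
  if (is.null(coefficients)) {
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    ll1 <- as.numeric(stats::logLik(fit))
  } else {
    ll1 <- logLikLogistic(coefficients[1L], coefficients[2L], x, y)
  }
  stat <- max(0, 2 * (ll1 - ll0))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       logLikFull = ll1, logLikNull = ll0)
}

# Bound on |slope| * sd(x): beyond this the likelihood is saturated to
# machine precision; coefficients exceeding it are reported capped.
.slopeCap <- 30

#' Fit a univariable logistic model for one gene
#'
#' Maximum-likelihood logistic fit of survival class on a single gene's
#' expression, with the pair-counting concordance AUC and the slope
#' likelihood-ratio p-value. Perfect/quasi-separation (common in 20-vs-20
#' extreme-group scans) is detected; coefficients are then reported capped
#' at a documented bound (|slope| * sd(x) = 30, intercept placing the
#' decision boundary mid-gap) and flagged, the rank-based AUC being
#' unaffected. A constant covariate yields slope 0, AUC 0.5 and an
#' uninformative flag.
#'
#' @param x numeric expression values over the cases.
#' @param y binary labels (1 = early event, 0 = long survivor); both classes
#'   non-empty.
#' @param gene optional gene id recorded in the result.
#' @return One-row data.frame: gene, intercept, slope, aucFolded,
#'   aucDirectional, statistic, pLRT, converged, separation, informative.
#' @export
fitGeneModel <- function(x, y, gene = NA_character_) {
  stopifnot(length(x) == length(y))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || sum(y) == 0L || sum(1L - y) == 0L)
    stop("labels must contain both classes (0 and 1)")
  if (!all(is.finite(x))) stop("expression values must be finite")
  x1 <- x[y == 1L]; x0 <- x[y == 0L]
  aDir <- pairwiseAUC(x1, x0, folded = FALSE)
  aFold <- max(aDir, 1 - aDir)
  sdx <- stats::sd(x)
  if (sdx == 0) {
    return(data.frame(gene = gene, intercept = stats::qlogis(mean(y)),
                      slope = 0, aucFolded = 0.5, aucDirectional = 0.5,
                      statistic = 0, pLRT = 1, converged = TRUE,
                      separation = FALSE, informative = FALSE,
                      stringsAsFactors = FALSE))
  }
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b0 <- unname(stats::coef(fit)[1L])
  b1 <- unname(stats::coef(fit)[2L])
  perfectSep <- aDir %in% c(0, 1)
  separation <- perfectSep || sepWarn || abs(b1) * sdx > .slopeCap
  if (separation && abs(b1) * sdx > .slopeCap) {
    # cap the slope; put the decision boundary at the midpoint of the
    # inter-class gap so predictions are preserved
    dir <- sign(b1)
    b1 <- dir * .slopeCap / sdx
    cut <- if (dir > 0) (min(x1) + max(x0)) / 2 else (max(x1) + min(x0)) / 2
    b0 <- -b1 * cut
  }
  lrt <- slopeLRT(x, y, coefficients = if (separation) c(b0, b1) else NULL)
  data.frame(gene = gene, intercept = b0, slope = b1, aucFolded = aFold,
             aucDirectional = aDir, statistic = lrt$statistic, pLRT = lrt$p,
             converged = fit$converged || separation, separation = separation,
             informative = TRUE, stringsAsFactors = FALSE)
}

#' Fit per-gene logistic models across an expression matrix
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param cases a labelled case set from [labelledCases()].
#' @param genes gene ids to fit (default: all genes in \code{m}).
#' @return data.frame with one row per gene (see [fitGeneModel()]).
#' @export
fitGeneModels <- function(m, cases, genes = geneIds(m)) {
  stopifnot(is(m, "ExpressionMatrix"))
  missing <- setdiff(cases$sample_id, sampleIds(m))
  if (length(missing))
    stop("cases absent from expression matrix: ", paste(missing, collapse = ", "))
  v <- exprValues(m)[genes, cases$sample_id, drop = FALSE]
  y <- cases$label
  out <- do.call(rbind, lapply(seq_along(genes), function(i)
    fitGeneModel(v[i, ], y, gene = genes[i])))
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of AUC distributions
#'
#' Compares the AUC distribution of a gene subset (e.g. keyword-flagged
#' immune genes) with a background distribution (all genes).
#'
#' @param aucSubset,aucBackground numeric vectors, each of length >= 2.
#' @return list with \code{statistic} (max ECDF gap D) and \code{p}
#'   (asymptotic two-sided p-value).
#' @export
ksCompare <- function(aucSubset, aucBackground) {
  if (length(aucSubset) < 2L || length(aucBackground) < 2L)
    stop("both AUC lists must have length >= 2")
  res <- suppressWarnings(stats::ks.test(aucSubset, aucBackground))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Confusion counts, sensitivity and specificity
#'
#' Class 1 (early event) is the positive class: sensitivity is the
#' proportion of early-event cases predicted correctly, specificity the
#' proportion of long-survivor cases predicted correctly.
#'
#' @param predicted,truth equal-length binary label vectors (0/1 or logical).
#' @return list with tp, fn, tn, fp, sensitivity, specificity.
#' @export
confusionCounts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  stopifnot(all(predicted %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  tp <- sum(predicted == 1L & truth == 1L)
  fn <- sum(predicted == 0L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  fp <- sum(predicted == 1L & truth == 0L)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
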