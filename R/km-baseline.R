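#' Kaplan-Meier product-limit survival curve
#'
#' Product-limit estimate under right censoring, as a step function defined
#' at the observed event times.
#'
#' @param times non-negative survival/follow-up times.
#' @param events logical event indicators (FALSE = right-censored).
#' @return data.frame: time, nRisk, nEvent, surv (estimate just after each
#'   listed time; only times at which the at-risk set changes are listed).
#' @export
kmEstimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
             surv = fit$surv)
}

# Balanced, deterministic q-quantile assignment on expression values:
# ranks with ties broken by stable sample order, sizes differing by <= 1.
quantileAssign <- function(values, q) {
  n <- length(values)
  ord <- order(values)                  # stable: ties keep input order
  grp <- integer(n)
  bounds <- floor(seq(0, n, length.out = q + 1L))
  for (i in seq_len(q)) grp[ord[(bounds[i] + 1L):bounds[i + 1L]]] <- i
  grp
}

#' Expression-quantile Kaplan-Meier test for one gene
#'
#' The conventional baseline the extreme-group logistic scan is compared
#' against: all joined cases are split into q near-equal expression
#' quantiles and the equality of their survival curves is tested with the
#' log-rank (Mantel-Cox) chi-square statistic on q - 1 degrees of freedom.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param gene gene id.
#' @param cohort a \linkS4class{CohortTable} whose sample ids join the
#'   expression columns.
#' @param q number of quantiles (default 4).
#' @return list: gene, q, assignment (named quantile per case), chisq, df,
#'   p, curves (list of per-quantile [kmEstimate()] tables),
#'   zeroEventQuantiles (labels of quantiles without any event, flagged but
#'   handled by the standard log-rank variance terms).
#' @export
kmQuantileTest <- function(m, gene, cohort, q = 4) {
  stopifnot(is(m, "ExpressionMatrix"), is(cohort, "CohortTable"), q >= 2)
  d <- cohortData(cohort)
  ids <- intersect(d$sample_id, sampleIds(m))
  if (length(ids) < q) stop("fewer joined cases than quantiles")
  d <- d[match(ids, d$sample_id), , drop = FALSE]
  x <- exprValues(m)[gene, ids]
  grp <- quantileAssign(x, q)
  sd <- survival::survdiff(
    survival::Surv(d$time, as.integer(d$event)) ~ grp)
  df <- length(unique(grp)) - 1L
  curves <- lapply(split(seq_along(ids), grp), function(i)
    kmEstimate(d$time[i], d$event[i]))
  zeroEvent <- names(which(vapply(split(d$event, grp), sum, 1) == 0))
  list(gene = gene, q = q,
       assignment = stats::setNames(grp, ids),
       chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(unname(sd$chisq), df = df, lower.tail = FALSE),
       curves = curves, zeroEventQuantiles = zeroEvent)
}

#' Rank genes by the KM quantile test
#'
#' Runs [kmQuantileTest()] for each gene and returns the per-gene statistic
#' table sorted by significance.
#'
#' @inheritParams kmQuantileTest
#' @param genes gene ids (default all).
#' @return data.frame: gene, chisq, p, sorted by chisq descending.
#' @export
kmRankGenes <- function(m, cohort, genes = geneIds(m), q = 4) {
  rows <- lapply(genes, function(g) {
    res <- kmQuantileTest(m, g, cohort, q = q)
    data.frame(gene = g, chisq = res$chisq, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$chisq, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between two gene rankings
#'
#' Compares e.g. the extreme-group logistic ranking with the KM quantile
#' ranking: how many of the top \code{topN} logistic genes also appear among
#' the top \code{topN} KM genes, with Jaccard indices at several depths.
#'
#' @param lrRanking,kmRanking ordered character vectors of gene ids over a
#'   common universe (best first).
#' @param topN primary comparison depth.
#' @param depths additional depths for the Jaccard profile (default
#'   \code{c(10, 20, 40)}).
#' @return list: topN, overlapCount, overlapGenes, jaccard (named numeric
#'   per depth).
#' @export
compareMethods <- function(lrRanking, kmRanking, topN,
                           depths = c(10, 20, 40)) {
  stopifnot(topN >= 1)
  ov <- intersect(utils::head(lrRanking, topN), utils::head(kmRanking, topN))
  jac <- vapply(depths, function(d) {
    a <- utils::head(lrRanking, d); b <- utils::head(kmRanking, d)
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  list(topN = topN, overlapCount = length(ov), overlapGenes = ov,
       jaccard = stats::setNames(jac, paste0("top", depths)))
}
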