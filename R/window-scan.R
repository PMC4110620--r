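#' Sequential sliding windows over an ordered case group
#'
#' All m - k + 1 consecutive rank windows: window i covers ranks
#' i .. i + k - 1 (e.g. m = 40, k = 20 gives the 21 windows 1-20, 2-21,
#' ..., 21-40). Cases near the middle of the group are sampled more often
#' than cases at the ends.
#'
#' @param group ordered character vector of m case ids (rank order, e.g.
#'   ascending survival time for the early group).
#' @param k window size, k <= m.
#' @param sourceGroup label recorded in the result ("early"/"late"/...).
#' @return A \linkS4class{WindowSet} of kind \code{"sequential"}.
#' @export
sequentialWindows <- function(group, k, sourceGroup = "early") {
  m <- length(group)
  k <- as.integer(k)
  if (k > m) stop(sprintf("window size %d exceeds group size %d", k, m))
  wins <- lapply(seq_len(m - k + 1L), function(i) group[i:(i + k - 1L)])
  new("WindowSet", windows = wins, kind = "sequential",
      sourceGroup = sourceGroup, windowSize = k, sourceSize = m)
}

#' Revolving (wrap-around) sliding windows
#'
#' Like [sequentialWindows()] but once fewer than k sequential cases remain
#' before the end of the group, the window wraps around to the start
#' (indices taken modulo m). This yields exactly m windows in which every
#' case appears exactly k times, removing the uneven sampling of the plain
#' sliding window while preserving survival order as much as possible.
#'
#' @inheritParams sequentialWindows
#' @return A \linkS4class{WindowSet} of kind \code{"revolving"}.
#' @export
revolvingWindows <- function(group, k, sourceGroup = "early") {
  m <- length(group)
  k <- as.integer(k)
  if (k > m) stop(sprintf("window size %d exceeds group size %d", k, m))
  wins <- lapply(seq_len(m), function(i)
    group[((i - 1L):(i + k - 2L)) %% m + 1L])
  new("WindowSet", windows = wins, kind = "revolving",
      sourceGroup = sourceGroup, windowSize = k, sourceSize = m)
}

#' Bootstrap window families
#'
#' Randomly and repeatedly selects groups of k cases from the m-case group
#' (without replacement within a window), an alternative to rank-based
#' windows when survival times are imprecise.
#'
#' @inheritParams sequentialWindows
#' @param B number of replicate windows (default 200).
#' @param seed integer seed.
#' @return A \linkS4class{WindowSet} of kind \code{"bootstrap"} with B
#'   windows.
#' @export
bootstrapWindows <- function(group, k, B = 200, seed = 1,
                             sourceGroup = "early") {
  m <- length(group)
  k <- as.integer(k)
  if (k > m) stop(sprintf("window size %d exceeds group size %d", k, m))
  set.seed(seed)
  wins <- lapply(seq_len(B), function(i) sample(group, k))
  new("WindowSet", windows = wins, kind = "bootstrap",
      sourceGroup = sourceGroup, windowSize = k, sourceSize = m)
}

#' Score genes by threshold hit counts over a window family
#'
#' For every gene and every window, the window's cases are compared with the
#' fixed opposing group and the folded concordance AUC of the gene's
#' expression is computed; the gene's score is the number of windows in
#' which the AUC exceeds \code{threshold}. The folded AUC of the raw values
#' equals the AUC of the per-window logistic model's fitted probabilities
#' (monotone link), so the hit count is exactly the count of window models
#' exceeding the accuracy threshold.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param moving a \linkS4class{WindowSet}.
#' @param fixed character vector of the constant opposing group's case ids;
#'   must be disjoint from every window.
#' @param threshold folded-AUC hit threshold in (0.5, 1) (default 0.8, the
#'   conventional bound for an excellent discriminatory model).
#' @param genes gene ids to score (default all).
#' @return data.frame: gene, hits, total, meanAUC; the per-window AUC matrix
#'   (genes x windows) is attached as \code{attr(x, "auc")}.
#' @export
scanWindows <- function(m, moving, fixed, threshold = 0.8,
                        genes = geneIds(m)) {
  stopifnot(is(m, "ExpressionMatrix"), is(moving, "WindowSet"))
  if (!(threshold > 0.5 && threshold < 1))
    stop("threshold must lie in (0.5, 1)")
  member <- unique(unlist(windows(moving)))
  if (length(intersect(member, fixed)))
    stop("window membership overlaps the fixed group: ",
         paste(utils::head(intersect(member, fixed), 5L), collapse = ", "))
  v <- exprValues(m)
  if (!all(c(member, fixed) %in% colnames(v)))
    stop("cases absent from expression matrix")
  v <- v[genes, , drop = FALSE]
  vFixed <- v[, fixed, drop = FALSE]
  aucs <- vapply(windows(moving), function(w)
    rowFoldedAUC(v[, w, drop = FALSE], vFixed), numeric(length(genes)))
  aucs <- matrix(aucs, nrow = length(genes),
                 dimnames = list(genes, NULL))
  out <- data.frame(gene = genes, hits = rowSums(aucs > threshold),
                    total = length(windows(moving)), meanAUC = rowMeans(aucs),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "auc") <- aucs
  out
}

#' Combine window scores from several scans
#'
#' Sums hit counts and totals gene-wise, e.g. the bidirectional design (40
#' revolving early-side windows vs the fixed 20 longest survivors plus 40
#' late-side windows vs the fixed 20 earliest deaths, 80 comparisons in
#' total).
#'
#' @param ... window-score data.frames from [scanWindows()], over the same
#'   genes.
#' @return data.frame: gene, hits, total, meanAUC (comparison-weighted);
#'   per-scan hit breakdown in columns \code{hits1}, \code{hits2}, ...
#' @export
combineScores <- function(...) {
  scans <- list(...)
  stopifnot(length(scans) >= 1L)
  genes <- scans[[1L]]$gene
  for (s in scans) {
    if (!identical(sort(s$gene), sort(genes)))
      stop("scans must cover the same genes")
  }
  aligned <- lapply(scans, function(s) s[match(genes, s$gene), ])
  hits <- Reduce(`+`, lapply(aligned, `[[`, "hits"))
  total <- Reduce(`+`, lapply(aligned, `[[`, "total"))
  meanAUC <- Reduce(`+`, lapply(aligned, function(s) s$meanAUC * s$total)) / total
  out <- data.frame(gene = genes, hits = hits, total = total,
                    meanAUC = meanAUC, stringsAsFactors = FALSE)
  for (i in seq_along(aligned)) out[[paste0("hits", i)]] <- aligned[[i]]$hits
  out
}

#' All-pairs window scan
#'
#' Every window of the early-side family is compared with every window of
#' the late-side family (|E| * |L| comparisons per gene; e.g. 30 revolving
#' windows per side give 900), yielding the full per-gene AUC distribution
#' plus threshold hit counts.
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param earlyWindows,lateWindows \linkS4class{WindowSet}s drawn from
#'   disjoint groups.
#' @param threshold folded-AUC hit threshold (default 0.8).
#' @param genes gene ids to score (default all).
#' @return data.frame as in [scanWindows()]; \code{attr(x, "auc")} is the
#'   genes x (|E| * |L|) AUC matrix.
#' @export
allPairsScan <- function(m, earlyWindows, lateWindows, threshold = 0.8,
                         genes = geneIds(m)) {
  stopifnot(is(m, "ExpressionMatrix"),
            is(earlyWindows, "WindowSet"), is(lateWindows, "WindowSet"))
  e <- unique(unlist(windows(earlyWindows)))
  l <- unique(unlist(windows(lateWindows)))
  if (length(intersect(e, l)))
    stop("window families overlap in membership: ",
         paste(utils::head(intersect(e, l), 5L), collapse = ", "))
  v <- exprValues(m)[genes, , drop = FALSE]
  combos <- expand.grid(e = seq_along(windows(earlyWindows)),
                        l = seq_along(windows(lateWindows)))
  aucs <- vapply(seq_len(nrow(combos)), function(i) {
    we <- windows(earlyWindows)[[combos$e[i]]]
    wl <- windows(lateWindows)[[combos$l[i]]]
    rowFoldedAUC(v[, we, drop = FALSE], v[, wl, drop = FALSE])
  }, numeric(length(genes)))
  aucs <- matrix(aucs, nrow = length(genes), dimnames = list(genes, NULL))
  out <- data.frame(gene = genes, hits = rowSums(aucs > threshold),
                    total = nrow(combos), meanAUC = rowMeans(aucs),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "auc") <- aucs
  out
}

#' Rank genes by window hit count
#'
#' @param scores window-score data.frame ([scanWindows()] or
#'   [combineScores()]), all rows on a common \code{total}.
#' @param minHits minimum hit count to retain a gene.
#' @return data.frame of retained genes sorted by hits descending, ties
#'   broken by mean AUC descending then gene id.
#' @export
rankGenes <- function(scores, minHits = 0) {
  if (length(unique(scores$total)) != 1L)
    stop("scores must share a common total comparison count")
  keep <- scores[scores$hits >= minHits, , drop = FALSE]
  ord <- order(-keep$hits, -keep$meanAUC, keep$gene)
  out <- keep[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
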