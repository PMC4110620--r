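#' Filter to highly variable, adequately expressed genes
#'
#' A gene passes when (a) its interquartile difference Q3 - Q1 across all
#' samples is at least \code{iqrMin} log units, and (b) more than
#' \code{floorFraction} of its values exceed \code{floorValue}. The floor
#' criterion is only meaningful on the raw log scale; on standard-score
#' matrices it is disabled and only the IQR criterion applies.
#'
#' Quartiles use linear interpolation (\code{stats::quantile} type 7), so
#' the pass/fail boundary is stated exactly and reproducible.
#'
#' @param m an \linkS4class{ExpressionMatrix} with at least 4 samples.
#' @param iqrMin minimum interquartile difference in log units (default 0.5).
#' @param floorValue expression floor on the log scale (default 6.6).
#' @param floorFraction required fraction of values above the floor, in
#'   (0, 1] (default 0.25; the criterion is strict: fraction must exceed it).
#' @return list with \code{genes} (character vector of passing gene ids, in
#'   matrix order) and \code{diagnostics} (data.frame: gene, iqr,
#'   fracAboveFloor, passIqr, passFloor, pass).
#' @export
filterVariableGenes <- function(m, iqrMin = 0.5, floorValue = 6.6,
                                floorFraction = 0.25) {
  stopifnot(is(m, "ExpressionMatrix"), iqrMin >= 0,
            floorFraction > 0, floorFraction <= 1)
  v <- exprValues(m)
  if (ncol(v) < 4L) stop("need at least 4 samples to compute quartiles")
  qs <- apply(v, 1L, stats::quantile, probs = c(0.25, 0.75), names = FALSE,
              type = 7)
  iqr <- qs[2L, ] - qs[1L, ]
  useFloor <- identical(scaleTag(m), "raw_log")
  frac <- rowMeans(v > floorValue)
  passIqr <- iqr >= iqrMin
  passFloor <- if (useFloor) frac > floorFraction else rep(TRUE, nrow(v))
  pass <- passIqr & passFloor
  diag <- data.frame(gene = rownames(v), iqr = iqr,
                     fracAboveFloor = if (useFloor) frac else NA_real_,
                     passIqr = passIqr, passFloor = passFloor, pass = pass,
                     row.names = NULL, stringsAsFactors = FALSE)
  list(genes = rownames(v)[pass], diagnostics = diag)
}
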