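#' Construct an ExpressionMatrix from a numeric matrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), log-scale expression.
#' @param scaleTag \code{"raw_log"} (default) or \code{"standard_score"}.
#' @param loadReport optional list of reader diagnostics stored in
#'   \code{metadata()}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(12, 7), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, scaleTag = "raw_log", loadReport = list()) {
  values <- as.matrix(values)
  se <- SummarizedExperiment(assays = list(exprs = values))
  out <- new("ExpressionMatrix", se, scaleTag = scaleTag)
  metadata(out)$loadReport <- loadReport
  validObject(out)
  out
}

#' Construct a CohortTable from a data.frame of clinical records
#'
#' @param data data.frame with at least \code{sample_id}, \code{time},
#'   \code{event}; extra columns (stage, adjuvant, subtype flags) are kept.
#' @param joinReport,selectionLog optional diagnostic lists.
#' @return A \linkS4class{CohortTable}.
#' @export
CohortTable <- function(data, joinReport = list(), selectionLog = list()) {
  data <- as.data.frame(data)
  data$sample_id <- as.character(data$sample_id)
  data$event <- as.logical(data$event)
  rownames(data) <- NULL
  new("CohortTable", data = data, joinReport = joinReport,
      selectionLog = selectionLog)
}

#' Accessors for extremeScan containers
#'
#' \code{exprValues} returns the genes x samples matrix; \code{scaleTag} the
#' scale label; \code{geneIds}/\code{sampleIds} the identifier vectors;
#' \code{cohortData} the clinical data.frame; \code{joinReport} and
#' \code{selectionLog} the reader/stratification diagnostics;
#' \code{windows} the list of window membership vectors.
#'
#' @param x an \linkS4class{ExpressionMatrix}, \linkS4class{CohortTable} or
#'   \linkS4class{WindowSet}.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setMethod("scaleTag", "ExpressionMatrix", function(x) x@scaleTag)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "CohortTable", function(x) x@data$sample_id)

#' @rdname accessors
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))
#' @rdname accessors
#' @export
setMethod("cohortData", "CohortTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("joinReport", function(x) standardGeneric("joinReport"))
#' @rdname accessors
#' @export
setMethod("joinReport", "CohortTable", function(x) x@joinReport)

#' @rdname accessors
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))
#' @rdname accessors
#' @export
setMethod("selectionLog", "CohortTable", function(x) x@selectionLog)

#' @rdname accessors
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))
#' @rdname accessors
#' @export
setMethod("windows", "WindowSet", function(x) x@windows)

#' Accessors for ExtremeGroups
#'
#' @param x an \linkS4class{ExtremeGroups} object.
#' @param extended logical; return the extended group of size m instead of
#'   the core group of size k.
#' @return Ordered character vector of sample ids (\code{earlyGroup} ascending
#'   survival time, \code{lateGroup} descending), or for
#'   \code{censoringSummary} a data.frame of censored counts per group.
#' @name group-accessors
NULL

#' @rdname group-accessors
#' @export
setGeneric("earlyGroup", function(x, extended = FALSE) standardGeneric("earlyGroup"))
#' @rdname group-accessors
#' @export
setMethod("earlyGroup", "ExtremeGroups", function(x, extended = FALSE)
  if (extended) x@earlyExtended else x@earlyCore)

#' @rdname group-accessors
#' @export
setGeneric("lateGroup", function(x, extended = FALSE) standardGeneric("lateGroup"))
#' @rdname group-accessors
#' @export
setMethod("lateGroup", "ExtremeGroups", function(x, extended = FALSE)
  if (extended) x@lateExtended else x@lateCore)

#' @rdname group-accessors
#' @export
setGeneric("censoringSummary", function(x) standardGeneric("censoringSummary"))
#' @rdname group-accessors
#' @export
setMethod("censoringSummary", "ExtremeGroups", function(x) x@censoringSummary)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), object@scaleTag))
})

setMethod("show", "CohortTable", function(object) {
  d <- object@data
  cat(sprintf("CohortTable: %d cases, %d events, %d censored\n",
              nrow(d), sum(d$event), sum(!d$event)))
  if (length(object@joinReport$unmatchedClinical))
    cat(sprintf("  unmatched clinical ids: %d\n",
                length(object@joinReport$unmatchedClinical)))
})

setMethod("show", "ExtremeGroups", function(object) {
  cat(sprintf("ExtremeGroups: cores %d + %d, extended %d + %d\n",
              length(object@earlyCore), length(object@lateCore),
              length(object@earlyExtended), length(object@lateExtended)))
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d %s windows of %d cases from %d-case '%s' group\n",
              length(object@windows), object@kind, object@windowSize,
              object@sourceSize, object@sourceGroup))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d cases (+%d contaminated), %d genes (%d signal, rho %.2f, delta %.2f sd), seed %d\n",
    object@nCases, object@nContamCases, object@nGenes, object@nSignalGenes,
    object@signalBlockRho, object@effectDelta, object@seed))
})

#' Subset an ExpressionMatrix
#'
#' Standard \code{[} subsetting is inherited from SummarizedExperiment and
#' preserves the scale tag.
#'
#' @param x ExpressionMatrix
#' @param i,j gene / sample indices
#' @param ... ignored
#' @param drop ignored
#' @return ExpressionMatrix
#' @export
setMethod("[", c("ExpressionMatrix", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  out <- callNextMethod()
  out@scaleTag <- x@scaleTag
  out
})
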