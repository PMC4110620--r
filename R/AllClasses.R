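#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata metadata<-
NULL

#' ExpressionMatrix: a log-scale genes x samples expression container
#'
#' Thin subclass of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}) of log-scale expression values, gene identifiers as row
#' names and sample identifiers as column names. The \code{scaleTag} slot
#' records whether columns are on the raw log scale (\code{"raw_log"}) or have
#' been standardised per sample to mean 0, sd 1 (\code{"standard_score"}).
#'
#' @slot scaleTag character, one of \code{"raw_log"}, \code{"standard_score"}.
#' @seealso [ExpressionMatrix()], [scaleArrays()], [readExpression()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(scaleTag = "character"),
  prototype = prototype(scaleTag = "raw_log")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@scaleTag) != 1L ||
      !object@scaleTag %in% c("raw_log", "standard_score"))
    msg <- c(msg, "scaleTag must be 'raw_log' or 'standard_score'")
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- assay(object, "exprs")
    if (!all(is.finite(v)))
      msg <- c(msg, "expression values must all be finite")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg) == 0L && identical(object@scaleTag, "standard_score") &&
        ncol(v) > 0L && nrow(v) > 1L) {
      mu <- colMeans(v)
      sdv <- apply(v, 2L, stats::sd)
      if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9))
        msg <- c(msg, "standard_score columns must have mean 0 and sd 1 (tol 1e-9)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CohortTable: per-case clinical records joined to expression samples
#'
#' Holds one row per clinical record with mandatory columns
#' \code{sample_id}, \code{time} (months, non-negative) and \code{event}
#' (logical: death / first recurrence observed), plus optional \code{stage}
#' (factor with levels I, II, III, unknown), \code{adjuvant} (logical) and any
#' number of logical subtype-flag columns. A join report records which
#' records matched an expression column.
#'
#' @slot data data.frame of clinical records.
#' @slot joinReport list with \code{matched}, \code{unmatchedClinical},
#'   \code{unmatchedExpression} character vectors (empty until joined).
#' @slot selectionLog list of per-criterion exclusion counts written by
#'   [applyStrata()].
#' @exportClass CohortTable
setClass("CohortTable",
  slots = c(data = "data.frame", joinReport = "list", selectionLog = "list"),
  prototype = prototype(joinReport = list(), selectionLog = list())
)

setValidity("CohortTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("missing mandatory columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if (any(is.na(d$time)) || any(d$time < 0))
    msg <- c(msg, "time must be non-negative and non-missing")
  if (any(is.na(d$event)))
    msg <- c(msg, "event must be defined (TRUE/FALSE) for every record")
  if (length(msg)) msg else TRUE
})

#' SelectionCriteria: stratification and extreme-group sizing
#'
#' @slot includeStages character vector of stage labels to keep
#'   (empty = keep all).
#' @slot requireNoAdjuvant logical; drop cases with adjuvant therapy.
#' @slot subtypeRequirements named list of required logical flag values.
#' @slot coreSize integer k, size of each core extreme group (default 20).
#' @slot extendedSize integer m >= k, size of each extended group (default 40).
#' @slot skipInitialEvents integer, number of earliest events to skip before
#'   forming the early groups (e.g. presumed perioperative deaths).
#' @slot earlyRequiresEvent logical; early groups admit only observed events.
#' @exportClass SelectionCriteria
setClass("SelectionCriteria",
  slots = c(
    includeStages = "character",
    requireNoAdjuvant = "logical",
    subtypeRequirements = "list",
    coreSize = "integer",
    extendedSize = "integer",
    skipInitialEvents = "integer",
    earlyRequiresEvent = "logical"
  ),
  prototype = prototype(
    includeStages = character(),
    requireNoAdjuvant = FALSE,
    subtypeRequirements = list(),
    coreSize = 20L,
    extendedSize = 40L,
    skipInitialEvents = 0L,
    earlyRequiresEvent = TRUE
  )
)

setValidity("SelectionCriteria", function(object) {
  msg <- character()
  if (object@coreSize < 1L) msg <- c(msg, "coreSize must be positive")
  if (object@extendedSize < object@coreSize)
    msg <- c(msg, "extendedSize must be >= coreSize")
  if (object@skipInitialEvents < 0L)
    msg <- c(msg, "skipInitialEvents must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ExtremeGroups: ordered extreme survival groups
#'
#' Early groups are ordered by ascending survival time (earliest event
#' first); late groups by descending time (longest survivor first). Cores are
#' prefixes of the extended groups, so rank order is preserved for window
#' construction.
#'
#' @slot earlyCore,lateCore,earlyExtended,lateExtended ordered character
#'   vectors of sample ids.
#' @slot times named numeric vector of survival times for all selected ids.
#' @slot censoringSummary data.frame of censored counts per group.
#' @exportClass ExtremeGroups
setClass("ExtremeGroups",
  slots = c(
    earlyCore = "character", lateCore = "character",
    earlyExtended = "character", lateExtended = "character",
    times = "numeric", censoringSummary = "data.frame"
  )
)

setValidity("ExtremeGroups", function(object) {
  msg <- character()
  if (length(object@earlyCore) != length(object@lateCore))
    msg <- c(msg, "core groups must be equal sized")
  if (length(object@earlyExtended) != length(object@lateExtended))
    msg <- c(msg, "extended groups must be equal sized")
  if (!all(object@earlyCore %in% object@earlyExtended))
    msg <- c(msg, "earlyCore must be contained in earlyExtended")
  if (!all(object@lateCore %in% object@lateExtended))
    msg <- c(msg, "lateCore must be contained in lateExtended")
  if (length(intersect(object@earlyExtended, object@lateExtended)))
    msg <- c(msg, "extended groups must be disjoint")
  tm <- object@times
  if (length(tm) &&
      all(c(object@earlyExtended, object@lateExtended) %in% names(tm)) &&
      length(object@earlyExtended) && length(object@lateExtended) &&
      max(tm[object@earlyExtended]) >= min(tm[object@lateExtended]))
    msg <- c(msg, "early and late extended groups overlap in survival time")
  if (length(msg)) msg else TRUE
})

#' WindowSet: a family of equal-size case windows over an ordered group
#'
#' @slot windows list of ordered character vectors, each of length
#'   \code{windowSize}.
#' @slot kind \code{"sequential"}, \code{"revolving"} or \code{"bootstrap"}.
#' @slot sourceGroup label of the group the windows are drawn from
#'   (\code{"early"}, \code{"late"} or free text).
#' @slot windowSize,sourceSize integers k and m.
#' @exportClass WindowSet
setClass("WindowSet",
  slots = c(
    windows = "list", kind = "character", sourceGroup = "character",
    windowSize = "integer", sourceSize = "integer"
  )
)

setValidity("WindowSet", function(object) {
  msg <- character()
  k <- object@windowSize
  if (!all(vapply(object@windows, length, 1L) == k))
    msg <- c(msg, "every window must have exactly windowSize cases")
  if (!object@kind %in% c("sequential", "revolving", "bootstrap"))
    msg <- c(msg, "kind must be sequential, revolving or bootstrap")
  n <- length(object@windows)
  if (object@kind == "sequential" && n != object@sourceSize - k + 1L)
    msg <- c(msg, "sequential window count must be m - k + 1")
  if (object@kind == "revolving" && n != object@sourceSize)
    msg <- c(msg, "revolving window count must be m")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic survival cohort generator
#'
#' Defaults mirror the cohorts the scanning method targets: roughly one
#' hundred cases, two thousand log2-scale genes with a correlated block of
#' twenty signal genes whose expression is higher in long survivors, and
#' right-censoring confined to the survivor class.
#'
#' @slot nCases even integer, cohort size before contamination.
#' @slot nGenes,nSignalGenes total and signal gene counts.
#' @slot signalBlockRho target marginal Pearson correlation among signal
#'   genes across the cohort, in [0, 1).
#' @slot effectDelta class-mean shift of signal genes in noise-sd units
#'   (survivors higher by default).
#' @slot noiseSd residual within-class standard deviation (log units).
#' @slot baselineMean baseline log2 expression level.
#' @slot censorRate fraction of long survivors right-censored, in [0, 1].
#' @slot outlierFlipCount number of cases whose expression-class linkage is
#'   inverted (their labels and survival times are untouched).
#' @slot nContamCases,nContamGenes,contamDelta optional stage-III-like
#'   contamination block: extra short-surviving cases that express the
#'   signal block at survivor level (decoupling it from outcome) and elevate
#'   a disjoint block of marker genes by \code{contamDelta} noise-sd units.
#' @slot seed integer seed making generation reproducible.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  slots = c(
    nCases = "integer", nGenes = "integer", nSignalGenes = "integer",
    signalBlockRho = "numeric", effectDelta = "numeric", noiseSd = "numeric",
    baselineMean = "numeric", censorRate = "numeric",
    outlierFlipCount = "integer",
    nContamCases = "integer", nContamGenes = "integer", contamDelta = "numeric",
    seed = "integer"
  ),
  prototype = prototype(
    nCases = 100L, nGenes = 2000L, nSignalGenes = 20L,
    signalBlockRho = 0.75, effectDelta = 2.5, noiseSd = 1,
    baselineMean = 7, censorRate = 0.5, outlierFlipCount = 0L,
    nContamCases = 0L, nContamGenes = 0L, contamDelta = 3,
    seed = 1L
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nSignalGenes > object@nGenes)
    msg <- c(msg, "nSignalGenes must not exceed nGenes")
  if (object@signalBlockRho < 0 || object@signalBlockRho >= 1)
    msg <- c(msg, "signalBlockRho must lie in [0, 1)")
  if (object@censorRate < 0 || object@censorRate > 1)
    msg <- c(msg, "censorRate must lie in [0, 1]")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (object@nCases < 4L) msg <- c(msg, "nCases must be at least 4")
  if (object@outlierFlipCount > object@nCases)
    msg <- c(msg, "outlierFlipCount must not exceed nCases")
  if (object@nContamGenes > 0L &&
      object@nSignalGenes + object@nContamGenes > object@nGenes)
    msg <- c(msg, "signal + contamination genes must not exceed nGenes")
  if (length(msg)) msg else TRUE
})
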