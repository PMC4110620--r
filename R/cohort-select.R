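#' Construct SelectionCriteria
#'
#' @param includeStages character vector of stage labels to retain (e.g.
#'   \code{c("I", "II")}); empty keeps all stages.
#' @param requireNoAdjuvant drop cases that received adjuvant therapy.
#' @param subtypeRequirements named list of logical flag requirements, e.g.
#'   \code{list(triple_negative = TRUE, T1 = TRUE, N0 = TRUE)}.
#' @param coreSize k, cases per core extreme group (default 20).
#' @param extendedSize m >= k, cases per extended group (default 40).
#' @param skipInitialEvents number of earliest events to skip before forming
#'   the early groups (models exclusion of presumed perioperative deaths).
#' @param earlyRequiresEvent early groups admit only observed events
#'   (default TRUE); long-survivor groups always admit censored records,
#'   whose observed time is a lower bound on survival.
#' @return A \linkS4class{SelectionCriteria}.
#' @export
SelectionCriteria <- function(includeStages = character(),
                              requireNoAdjuvant = FALSE,
                              subtypeRequirements = list(),
                              coreSize = 20, extendedSize = 40,
                              skipInitialEvents = 0,
                              earlyRequiresEvent = TRUE) {
  new("SelectionCriteria",
      includeStages = as.character(includeStages),
      requireNoAdjuvant = requireNoAdjuvant,
      subtypeRequirements = subtypeRequirements,
      coreSize = as.integer(coreSize),
      extendedSize = as.integer(extendedSize),
      skipInitialEvents = as.integer(skipInitialEvents),
      earlyRequiresEvent = earlyRequiresEvent)
}

#' Stratify a cohort on clinical criteria
#'
#' Removes records failing any criterion (stage membership, adjuvant
#' therapy, subtype flags) and logs per-criterion exclusion counts, so a
#' clinically homogeneous subset remains in which survival is the dominant
#' variable.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param criteria a \linkS4class{SelectionCriteria}.
#' @return The filtered \linkS4class{CohortTable}; \code{selectionLog(x)}
#'   holds exclusion counts per criterion.
#' @export
applyStrata <- function(cohort, criteria) {
  stopifnot(is(cohort, "CohortTable"), is(criteria, "SelectionCriteria"))
  d <- cohortData(cohort)
  keep <- rep(TRUE, nrow(d))
  log <- list(input = nrow(d))
  if (length(criteria@includeStages)) {
    if (is.null(d$stage)) stop("criteria include stages but cohort has no stage column")
    ok <- as.character(d$stage) %in% criteria@includeStages
    log$stage <- sum(keep & !ok)
    keep <- keep & ok
  }
  if (criteria@requireNoAdjuvant) {
    if (is.null(d$adjuvant)) stop("criteria require no adjuvant therapy but cohort has no adjuvant column")
    ok <- !d$adjuvant
    log$adjuvant <- sum(keep & !ok)
    keep <- keep & ok
  }
  for (flag in names(criteria@subtypeRequirements)) {
    if (is.null(d[[flag]]))
      stop("criteria require flag absent from cohort: ", flag)
    ok <- d[[flag]] == criteria@subtypeRequirements[[flag]]
    log[[flag]] <- sum(keep & !ok)
    keep <- keep & ok
  }
  log$retained <- sum(keep)
  if (!any(keep))
    stop("stratification removed every case; relax the selection criteria")
  CohortTable(d[keep, , drop = FALSE], joinReport = joinReport(cohort),
              selectionLog = log)
}

#' Select the extreme survival groups of a cohort
#'
#' Cases are ranked by survival (or event-free) time. The early groups are
#' the shortest times among observed events, after skipping the first
#' \code{skipInitialEvents} events; the late groups are the longest times,
#' censored records included (their observed time is a lower bound, so a
#' long censored follow-up still certifies long survival). Cores of size k
#' are prefixes of the extended groups of size m, and ordering is retained
#' for window construction. Groups are always equal sized; no arbitrary time
#' cut-off is involved, only ranks.
#'
#' Ties on time are broken by events before censored records (for the early
#' extreme), then by stable input order, making selection deterministic.
#'
#' @param cohort a \linkS4class{CohortTable} (typically after
#'   [applyStrata()]).
#' @param criteria a \linkS4class{SelectionCriteria}.
#' @return An \linkS4class{ExtremeGroups}.
#' @export
selectExtremes <- function(cohort, criteria) {
  stopifnot(is(cohort, "CohortTable"), is(criteria, "SelectionCriteria"))
  d <- cohortData(cohort)
  k <- criteria@coreSize
  m <- criteria@extendedSize
  ordEarly <- order(d$time, !d$event)       # ascending time, events first
  earlyPool <- ordEarly
  if (criteria@earlyRequiresEvent) earlyPool <- ordEarly[d$event[ordEarly]]
  skip <- criteria@skipInitialEvents
  if (skip > 0L) earlyPool <- earlyPool[-seq_len(min(skip, length(earlyPool)))]
  if (length(earlyPool) < m)
    stop(sprintf("insufficient early cases: need %d, have %d eligible", m,
                 length(earlyPool)))
  earlyExt <- earlyPool[seq_len(m)]
  ordLate <- order(-d$time)                  # descending time, stable ties
  if (length(ordLate) < m)
    stop(sprintf("insufficient late cases: need %d, have %d", m, length(ordLate)))
  lateExt <- ordLate[seq_len(m)]
  if (length(intersect(earlyExt, lateExt)))
    stop("extreme groups overlap; cohort too small for the requested sizes")
  ids <- d$sample_id
  times <- stats::setNames(d$time, ids)
  cens <- data.frame(
    group = c("early_core", "late_core", "early_extended", "late_extended"),
    censored = c(sum(!d$event[earlyExt[seq_len(k)]]),
                 sum(!d$event[lateExt[seq_len(k)]]),
                 sum(!d$event[earlyExt]), sum(!d$event[lateExt])),
    size = c(k, k, m, m))
  new("ExtremeGroups",
      earlyCore = ids[earlyExt[seq_len(k)]],
      lateCore = ids[lateExt[seq_len(k)]],
      earlyExtended = ids[earlyExt],
      lateExtended = ids[lateExt],
      times = times[ids[c(earlyExt, lateExt)]],
      censoringSummary = cens)
}

#' Binary class labels for a two-group comparison
#'
#' Builds the labelled case set per-gene logistic models are fitted on:
#' class 1 = early event, class 0 = long survivor.
#'
#' @param class1,class0 character vectors of sample ids (disjoint,
#'   non-empty).
#' @return data.frame with columns \code{sample_id} and \code{label} (1/0),
#'   class-1 cases first, input order preserved within class.
#' @export
labelledCases <- function(class1, class0) {
  stopifnot(length(class1) > 0, length(class0) > 0)
  if (length(intersect(class1, class0)))
    stop("classes must be disjoint")
  data.frame(sample_id = c(class1, class0),
             label = rep(c(1L, 0L), c(length(class1), length(class0))),
             stringsAsFactors = FALSE)
}
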