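#' Read a delimited expression matrix, optionally collapsing probes to genes
#'
#' Reads a tab- or comma-separated numeric table whose first column holds
#' probe or gene identifiers and whose header row holds sample identifiers
#' (the layout of a GEO series-matrix value block). When a probe-to-gene map
#' is supplied, rows mapping to the same gene are replaced by their
#' arithmetic mean per sample (the data are assumed log scale, so means are
#' means of logs) and probes without a mapping are dropped and counted in the
#' load report.
#'
#' @param path path to the expression table (.tsv/.txt tab-separated, .csv
#'   comma-separated).
#' @param probeMap optional probe-to-gene map: a two-column data.frame
#'   (\code{probe}, \code{gene}) or the path of a two-column delimited file.
#' @return An \linkS4class{ExpressionMatrix} with \code{scaleTag = "raw_log"};
#'   \code{metadata(x)$loadReport} records row/column counts and dropped
#'   probes.
#' @export
readExpression <- function(path, probeMap = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  ids <- raw[[1L]]
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in header: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  num <- matrix(num, nrow = length(ids),
                dimnames = list(ids, sampleIds))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], sampleIds[bad[1L, 2L]]))
  if (anyNA(num))
    stop("missing values in expression table are not supported")
  report <- list(nRows = nrow(num), nSamples = ncol(num))
  if (!is.null(probeMap)) {
    collapsed <- collapseProbes(num, probeMap)
    num <- collapsed$values
    report <- c(report, collapsed$report)
  } else if (anyDuplicated(ids)) {
    stop("duplicate row identifiers without a probe map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ExpressionMatrix(num, scaleTag = "raw_log", loadReport = report)
}

#' Collapse probe rows to gene rows by arithmetic mean
#'
#' @param values numeric matrix with probe ids as rownames.
#' @param probeMap two-column data.frame or file path (probe, gene).
#' @return list with the collapsed \code{values} matrix (gene rows, in first
#'   appearance order of each gene) and a \code{report} list counting mapped
#'   genes and dropped probes.
#' @export
collapseProbes <- function(values, probeMap) {
  if (is.character(probeMap) && length(probeMap) == 1L) {
    sep <- if (grepl("\\.csv$", probeMap, ignore.case = TRUE)) "," else "\t"
    probeMap <- utils::read.table(probeMap, header = TRUE, sep = sep,
                                  colClasses = "character", check.names = FALSE)
  }
  probeMap <- as.data.frame(probeMap)
  if (ncol(probeMap) < 2L) stop("probeMap needs columns (probe, gene)")
  map <- stats::setNames(as.character(probeMap[[2L]]),
                         as.character(probeMap[[1L]]))
  probes <- rownames(values)
  gene <- map[probes]
  keep <- !is.na(gene) & nzchar(gene)
  dropped <- probes[!keep]
  v <- values[keep, , drop = FALSE]
  g <- gene[keep]
  geneOrder <- unique(g)
  out <- rowsum(v, group = factor(g, levels = geneOrder), reorder = FALSE) /
    as.vector(table(factor(g, levels = geneOrder)))
  rownames(out) <- geneOrder
  list(values = out,
       report = list(nProbes = length(probes), nGenes = length(geneOrder),
                     nDroppedProbes = length(dropped),
                     droppedProbes = dropped))
}

#' Standardise each sample column to mean 0, sd 1
#'
#' Each sample (column) is transformed to \eqn{(x - \bar x)/s} with the n-1
#' sample standard deviation, so arrays originating from different series
#' become comparable standard scores.
#'
#' @param m an \linkS4class{ExpressionMatrix} with \code{scaleTag "raw_log"}.
#' @return An \linkS4class{ExpressionMatrix} with
#'   \code{scaleTag "standard_score"}.
#' @export
scaleArrays <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (scaleTag(m) != "raw_log")
    stop("scaleArrays expects raw_log input; matrix is already standardised")
  v <- exprValues(m)
  sdv <- apply(v, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance sample column(s): ",
         paste(colnames(v)[sdv == 0], collapse = ", "))
  scaled <- scale(v, center = TRUE, scale = TRUE)
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  ExpressionMatrix(scaled, scaleTag = "standard_score",
                   loadReport = metadata(m)$loadReport)
}

#' Read a clinical table and join it to an expression matrix
#'
#' @param path CSV/TSV file of clinical records.
#' @param schema named list mapping the mandatory roles \code{id},
#'   \code{time}, \code{event} (and optionally \code{stage},
#'   \code{adjuvant}, plus a character vector \code{flags} of logical
#'   subtype-flag columns) to column names in the file.
#' @param expression optional \linkS4class{ExpressionMatrix}; when supplied,
#'   the join report lists clinical ids without an expression column and vice
#'   versa. Unmatched records are reported, never dropped.
#' @return A \linkS4class{CohortTable}.
#' @details \code{event} accepts logical, 0/1, or the strings
#'   yes/no/true/false/dead/alive/1/0 (case-insensitive). \code{stage} is
#'   normalised to the levels I, II, III, unknown; unrecognised labels map to
#'   unknown.
#' @export
readClinical <- function(path, schema = list(id = "sample_id", time = "time",
                                             event = "event"),
                         expression = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (role in c("id", "time", "event")) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("schema error: no column '%s' for mandatory role '%s'",
                   if (is.null(col)) "?" else col, role))
  }
  d <- data.frame(sample_id = as.character(raw[[schema$id]]),
                  time = as.numeric(raw[[schema$time]]),
                  event = parseEvent(raw[[schema$event]]),
                  stringsAsFactors = FALSE)
  if (any(is.na(d$time) | d$time < 0)) {
    bad <- d$sample_id[is.na(d$time) | d$time < 0]
    stop("negative or missing survival time for record(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(schema$stage) && schema$stage %in% names(raw))
    d$stage <- parseStage(raw[[schema$stage]])
  if (!is.null(schema$adjuvant) && schema$adjuvant %in% names(raw))
    d$adjuvant <- parseEvent(raw[[schema$adjuvant]])
  for (fl in schema$flags %||% character())
    if (fl %in% names(raw)) d[[fl]] <- parseEvent(raw[[fl]])
  jr <- list()
  if (!is.null(expression)) {
    ids <- sampleIds(expression)
    jr <- list(matched = intersect(d$sample_id, ids),
               unmatchedClinical = setdiff(d$sample_id, ids),
               unmatchedExpression = setdiff(ids, d$sample_id))
  }
  CohortTable(d, joinReport = jr)
}

parseEvent <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes", "y", "dead", "event", "recurrence")] <- TRUE
  out[s %in% c("0", "false", "f", "no", "n", "alive", "censored", "none")] <- FALSE
  if (anyNA(out)) stop("unparseable event/flag value(s): ",
                       paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

parseStage <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s[s %in% c("1", "I", "IA", "IB", "STAGE I")] <- "I"
  s[s %in% c("2", "II", "IIA", "IIB", "STAGE II")] <- "II"
  s[s %in% c("3", "III", "IIIA", "IIIB", "STAGE III")] <- "III"
  s[!s %in% c("I", "II", "III")] <- "unknown"
  factor(s, levels = c("I", "II", "III", "unknown"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag genes whose annotation matches any of a set of keywords
#'
#' Case-insensitive substring search over free-text gene descriptions (e.g.
#' the terms "immuno", "lymph", "B-cell", "T-cell" select an immune gene
#' set), unioned with an explicit list of extra genes restricted to the
#' annotation/expression universe.
#'
#' @param annotation data.frame with columns \code{gene_id} and
#'   \code{description}; duplicate gene_ids have their descriptions
#'   concatenated.
#' @param keywords non-empty character vector of search terms.
#' @param extraGenes gene ids added regardless of description.
#' @param universe optional gene universe (defaults to annotation gene ids)
#'   to which \code{extraGenes} are restricted.
#' @return Character vector of flagged gene ids (sorted, unique).
#' @export
flagGenesByKeyword <- function(annotation, keywords, extraGenes = character(),
                               universe = NULL) {
  keywords <- trimws(keywords)
  keywords <- keywords[nzchar(keywords)]
  if (length(keywords) == 0L) stop("keywords must be non-empty")
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("gene_id", "description") %in% names(annotation)))
  desc <- vapply(split(as.character(annotation$description),
                       as.character(annotation$gene_id)),
                 paste, "", collapse = " ")
  lowDesc <- tolower(desc)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k)
    grepl(k, lowDesc, fixed = TRUE)))
  universe <- universe %||% names(desc)
  sort(unique(c(names(desc)[hit], intersect(extraGenes, universe))))
}

#' Write an ExpressionMatrix / CohortTable to delimited text
#'
#' \code{writeExpression} writes the TSV layout \code{readExpression} reads
#' (first column \code{gene_id}, header = sample ids); \code{writeClinical}
#' writes a CSV \code{readClinical} can read back with the default schema.
#'
#' @param m ExpressionMatrix; \code{cohort} CohortTable.
#' @param cohort CohortTable.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeExpression <- function(m, path) {
  v <- exprValues(m)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
writeClinical <- function(cohort, path) {
  utils::write.table(cohortData(cohort), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
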