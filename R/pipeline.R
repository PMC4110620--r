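#' Default run configuration
#'
#' Returns the full default config list; [runPipeline()] deep-merges the
#' user's config over these values. Fields: \code{input} (either
#' \code{expressionPath}/\code{clinicalPath}/\code{schema}/\code{probeMapPath}
#' or in-memory \code{expression}/\code{cohort} objects), \code{selection}
#' (stage list, group sizes, event skipping), \code{filter} (enabled,
#' iqrMin, floorValue, floorFraction), \code{scan} (mode
#' sequential/revolving/allpairs/bootstrap, threshold, minHits,
#' bootstrapB), \code{validation} (enabled, topGenes), \code{km} (enabled,
#' q, topN), \code{seed}, \code{outputDir}.
#'
#' @return Nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    input = list(expressionPath = NULL, clinicalPath = NULL,
                 probeMapPath = NULL,
                 schema = list(id = "sample_id", time = "time",
                               event = "event", stage = "stage",
                               adjuvant = "adjuvant")),
    selection = list(includeStages = c("I", "II"), requireNoAdjuvant = FALSE,
                     coreSize = 20, extendedSize = 40, skipInitialEvents = 0,
                     earlyRequiresEvent = TRUE),
    filter = list(enabled = TRUE, iqrMin = 0.5, floorValue = 6.6,
                  floorFraction = 0.25),
    scan = list(mode = "revolving", threshold = 0.8, minHits = 20,
                bootstrapB = 200),
    validation = list(enabled = TRUE, topGenes = 24),
    km = list(enabled = TRUE, q = 4, topN = 40),
    seed = 1,
    outputDir = NULL
  )
}

mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read a run configuration from JSON or YAML
#'
#' @param path path to a .json or .yaml/.yml config file.
#' @return Config list (not yet merged with [defaultConfig()]).
#' @export
readConfig <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

writeCsv <- function(df, dir, name) {
  if (!is.null(dir))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Sorted accuracy table of per-gene logistic models
#'
#' Sorts per-gene models by folded AUC descending (the sorted accuracy
#' curve of an initial core-group comparison) and reports how many genes
#' reach the accuracy threshold.
#'
#' @param models data.frame from [fitGeneModels()].
#' @param threshold accuracy threshold for the count (default 0.8).
#' @return The sorted data.frame; \code{attr(x, "countAboveThreshold")}
#'   gives the number of genes with folded AUC >= threshold.
#' @export
sortedAccuracyTable <- function(models, threshold = 0.8) {
  out <- models[order(-models$aucFolded, models$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "countAboveThreshold") <- sum(out$aucFolded >= threshold)
  out
}

#' Run the full extreme-group scanning pipeline
#'
#' Executes, in order: load, stratify, select extremes, variable-gene
#' filter, initial core-group logistic scan (sorted accuracy table),
#' window scan(s), gene ranking, validation suite (leave-one-out,
#' split-half, prediction clustering, anchor correlations), KM quantile
#' baseline and the method-comparison report. Each stage's parameters and
#' outputs are logged; any stage error aborts with a stage-tagged message.
#'
#' The window scan is bidirectional for modes \code{"sequential"},
#' \code{"revolving"} and \code{"bootstrap"}: moving windows from the
#' extended early group are compared against the fixed late core, and
#' moving windows from the extended late group against the fixed early
#' core (e.g. 40 + 40 revolving windows = 80 comparisons per gene). Mode
#' \code{"allpairs"} compares every early-side window with every late-side
#' window instead.
#'
#' @param config nested list (merged over [defaultConfig()]), or the path
#'   of a JSON/YAML config file. Supply input data either as file paths
#'   (\code{input$expressionPath}, \code{input$clinicalPath}) or as
#'   in-memory objects (\code{input$expression}, \code{input$cohort}).
#' @return Invisible list: config, expression, cohort, groups, filter,
#'   initialModels, scanScores, ranking, validation, km, comparison, log.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- mergeConfig(defaultConfig(), config)
  dir <- cfg$outputDir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  set.seed(as.integer(cfg$seed))

  expr <- stageError("load", {
    if (!is.null(cfg$input$expression)) cfg$input$expression
    else readExpression(cfg$input$expressionPath,
                        probeMap = cfg$input$probeMapPath)
  })
  cohort <- stageError("load", {
    if (!is.null(cfg$input$cohort)) cfg$input$cohort
    else readClinical(cfg$input$clinicalPath, schema = cfg$input$schema,
                      expression = expr)
  })
  log$load <- list(genes = nrow(expr), samples = ncol(expr),
                   cases = nrow(cohortData(cohort)))

  crit <- SelectionCriteria(
    includeStages = cfg$selection$includeStages %||% character(),
    requireNoAdjuvant = isTRUE(cfg$selection$requireNoAdjuvant),
    coreSize = cfg$selection$coreSize,
    extendedSize = cfg$selection$extendedSize,
    skipInitialEvents = cfg$selection$skipInitialEvents,
    earlyRequiresEvent = !isFALSE(cfg$selection$earlyRequiresEvent))
  strat <- stageError("stratify", applyStrata(cohort, crit))
  log$stratify <- selectionLog(strat)

  groups <- stageError("select_extremes", selectExtremes(strat, crit))
  writeCsv(censoringSummary(groups), dir, "groups_censoring.csv")
  if (!is.null(dir)) {
    memb <- data.frame(
      sample_id = c(earlyGroup(groups, TRUE), lateGroup(groups, TRUE)),
      group = rep(c("early", "late"),
                  each = length(earlyGroup(groups, TRUE))),
      core = c(earlyGroup(groups, TRUE) %in% earlyGroup(groups),
               lateGroup(groups, TRUE) %in% lateGroup(groups)))
    writeCsv(memb, dir, "group_membership.csv")
  }

  filterRes <- stageError("filter", {
    if (isTRUE(cfg$filter$enabled))
      filterVariableGenes(expr, iqrMin = cfg$filter$iqrMin,
                          floorValue = cfg$filter$floorValue,
                          floorFraction = cfg$filter$floorFraction)
    else list(genes = geneIds(expr), diagnostics = NULL)
  })
  genes <- filterRes$genes
  log$filter <- list(enabled = isTRUE(cfg$filter$enabled),
                     retained = length(genes))
  if (length(genes) == 0L) stop("[stage: filter] no genes retained")

  cases <- labelledCases(earlyGroup(groups), lateGroup(groups))
  initial <- stageError("initial_scan",
    sortedAccuracyTable(fitGeneModels(expr, cases, genes = genes),
                        threshold = cfg$scan$threshold))
  log$initial_scan <- list(
    genes = nrow(initial),
    countAboveThreshold = attr(initial, "countAboveThreshold"))
  writeCsv(initial, dir, "initial_models.csv")

  mode <- cfg$scan$mode
  mkWindows <- function(group, label) switch(mode,
    sequential = sequentialWindows(group, crit@coreSize, sourceGroup = label),
    revolving = revolvingWindows(group, crit@coreSize, sourceGroup = label),
    allpairs = revolvingWindows(group, crit@coreSize, sourceGroup = label),
    bootstrap = bootstrapWindows(group, crit@coreSize, B = cfg$scan$bootstrapB,
                                 seed = as.integer(cfg$seed) +
                                   (label == "late"), sourceGroup = label),
    stop("unknown scan mode: ", mode))
  scanScores <- stageError("window_scan", {
    ew <- mkWindows(earlyGroup(groups, TRUE), "early")
    lw <- mkWindows(lateGroup(groups, TRUE), "late")
    if (mode == "allpairs") {
      allPairsScan(expr, ew, lw, threshold = cfg$scan$threshold, genes = genes)
    } else {
      combineScores(
        scanWindows(expr, ew, lateGroup(groups), threshold = cfg$scan$threshold,
                    genes = genes),
        scanWindows(expr, lw, earlyGroup(groups), threshold = cfg$scan$threshold,
                    genes = genes))
    }
  })
  log$window_scan <- list(mode = mode,
                          comparisons = unique(scanScores$total))
  writeCsv(scanScores[, setdiff(names(scanScores), "auc")], dir,
           "window_scores.csv")

  ranking <- stageError("rank_genes",
                        rankGenes(scanScores, minHits = cfg$scan$minHits))
  log$rank_genes <- list(minHits = cfg$scan$minHits, retained = nrow(ranking))
  writeCsv(ranking, dir, "gene_ranking.csv")

  validation <- NULL
  if (isTRUE(cfg$validation$enabled)) {
    validation <- stageError("validation", {
      top <- utils::head(
        rankGenes(scanScores, minHits = 0)$gene, cfg$validation$topGenes)
      loo <- leaveOneOut(expr, cases, genes = top)
      sh <- splitHalf(expr, cases, genes = top)
      clust <- if (length(top) >= 2L) clusterPredictionPatterns(loo) else NULL
      anchor <- top[1L]
      corr <- if (length(top) >= 2L)
        geneCorrelations(expr, anchor, others = setdiff(top, anchor),
                         samples = cases$sample_id) else NULL
      list(genes = top, loo = loo, looAccuracy = looAccuracy(loo),
           caseConsensus = caseConsensus(loo), splitHalf = sh,
           clustering = clust, anchor = anchor, correlations = corr)
    })
    log$validation <- list(genes = length(validation$genes),
                           meanLooAccuracy = mean(validation$looAccuracy))
    if (!is.null(dir)) {
      writeCsv(data.frame(gene = rownames(validation$loo),
                          validation$loo * 1, check.names = FALSE),
               dir, "loo_matrix.csv")
      writeCsv(validation$splitHalf, dir, "split_half.csv")
      if (!is.null(validation$correlations))
        writeCsv(validation$correlations, dir, "correlations.csv")
    }
  }

  km <- NULL; comparison <- NULL
  if (isTRUE(cfg$km$enabled)) {
    km <- stageError("km_baseline",
                     kmRankGenes(expr, strat, genes = genes, q = cfg$km$q))
    writeCsv(km, dir, "km_ranking.csv")
    comparison <- stageError("compare_methods",
      compareMethods(rankGenes(scanScores, minHits = 0)$gene, km$gene,
                     topN = cfg$km$topN))
    log$km <- list(q = cfg$km$q, topN = cfg$km$topN,
                   overlap = comparison$overlapCount)
  }

  if (!is.null(dir)) {
    jsonlite::write_json(cfg[setdiff(names(cfg), "input")],
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         null = "null", digits = NA)
    jsonlite::write_json(log, file.path(dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(config = cfg, expression = expr, cohort = strat,
                 groups = groups, filter = filterRes, initialModels = initial,
                 scanScores = scanScores, ranking = ranking,
                 validation = validation, km = km, comparison = comparison,
                 log = log))
}
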