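#' Construct a SyntheticSpec
#'
#' Defaults describe the cohort structure the scanning method targets: 100
#' cases split evenly into an early-event class (all deaths within 24
#' months) and a long-survivor class (all beyond 72 months, half
#' right-censored), 2000 log2-scale genes of which 20 form a correlated
#' signal block (marginal Pearson correlation 0.75) shifted 2.5 noise-sd
#' units higher in survivors.
#'
#' @param nCases,nGenes,nSignalGenes cohort and gene-universe sizes.
#' @param signalBlockRho target marginal correlation among signal genes.
#' @param effectDelta class-mean shift in noise-sd units (positive = higher
#'   in survivors).
#' @param noiseSd,baselineMean residual sd and baseline log2 level.
#' @param censorRate fraction of survivors right-censored.
#' @param outlierFlipCount cases whose expression-class linkage is inverted.
#' @param nContamCases,nContamGenes,contamDelta optional stage-III-like
#'   contamination block (see \linkS4class{SyntheticSpec}).
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
SyntheticSpec <- function(nCases = 100, nGenes = 2000, nSignalGenes = 20,
                          signalBlockRho = 0.75, effectDelta = 2.5,
                          noiseSd = 1, baselineMean = 7, censorRate = 0.5,
                          outlierFlipCount = 0, nContamCases = 0,
                          nContamGenes = 0, contamDelta = 3, seed = 1) {
  new("SyntheticSpec",
      nCases = as.integer(nCases), nGenes = as.integer(nGenes),
      nSignalGenes = as.integer(nSignalGenes),
      signalBlockRho = signalBlockRho, effectDelta = effectDelta,
      noiseSd = noiseSd, baselineMean = baselineMean,
      censorRate = censorRate,
      outlierFlipCount = as.integer(outlierFlipCount),
      nContamCases = as.integer(nContamCases),
      nContamGenes = as.integer(nContamGenes), contamDelta = contamDelta,
      seed = as.integer(seed))
}

# Residual factor loading that makes the marginal inter-signal-gene
# correlation equal rho given the class-mean shift delta (balanced classes):
# marginal corr = (delta^2/4 + rhoRes) / (delta^2/4 + 1).
residualRho <- function(rho, delta) {
  c2 <- delta^2 / 4
  rhoRes <- rho * (c2 + 1) - c2
  if (rhoRes < 0)
    stop(sprintf(
      "infeasible correlation: class shift %.2f alone forces correlation %.3f > target %.3f",
      delta, c2 / (c2 + 1), rho))
  rhoRes
}

#' Generate a synthetic survival cohort with planted signal genes
#'
#' Survival times are exponential within class with a gap enforcing the
#' extreme-group separation: early events are deaths within 24 months
#' (event observed), survivors live beyond 72 months with a fraction
#' right-censored uniformly over follow-up. Signal genes share a per-case
#' latent factor (inducing the requested marginal correlation) and are
#' shifted by \code{effectDelta} noise-sd units, higher in survivors; the
#' remaining genes are independent noise. Outlier cases have the
#' expression-class linkage inverted while keeping their labels and times.
#' An optional contamination block adds stage-III-like cases: short
#' survival despite survivor-level signal-gene expression (the protective
#' signal no longer determines outcome in advanced disease), plus a
#' disjoint block of marker genes elevated only in those cases.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{expression} (\linkS4class{ExpressionMatrix},
#'   raw_log), \code{cohort} (\linkS4class{CohortTable} with stage I/II for
#'   core cases, III for contaminated ones) and \code{truth} (list:
#'   signalGenes, contamGenes, outliers, class per case
#'   ("early"/"late"/"contam")).
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  nE <- spec@nCases %/% 2L
  nL <- spec@nCases - nE
  nC <- spec@nContamCases
  n <- spec@nCases + nC
  ids <- sprintf("case%03d", seq_len(n))
  cls <- c(rep("early", nE), rep("late", nL), rep("contam", nC))

  # survival: truncated-exponential early deaths (< 24 mo), survivors with a
  # gap (> 72 mo), contaminated cases short-lived like aggressive disease
  rexpTrunc <- function(k, rate, upper)
    stats::qexp(stats::runif(k) * stats::pexp(upper, rate), rate)
  timeE <- rexpTrunc(nE, 1 / 10, 24)
  timeL <- 72 + stats::rexp(nL, 1 / 36)
  eventL <- stats::runif(nL) >= spec@censorRate
  timeC <- if (nC) rexpTrunc(nC, 1 / 12, 36) else numeric()
  time <- c(timeE, timeL, timeC)
  event <- c(rep(TRUE, nE), eventL, rep(TRUE, nC))
  stage <- factor(c(sample(c("I", "II"), nE + nL, replace = TRUE),
                    rep("III", nC)), levels = c("I", "II", "III", "unknown"))

  # class indicator used for expression: survivors high; contaminated cases
  # express the signal block at survivor level despite dying early (the
  # protective signal is decoupled from outcome in advanced disease);
  # outliers inverted
  s <- c(rep(-0.5, nE), rep(0.5, nL), rep(0.5, nC))
  outliers <- character()
  if (spec@outlierFlipCount > 0L) {
    flip <- sample(seq_len(nE + nL), spec@outlierFlipCount)
    s[flip] <- -s[flip]
    outliers <- ids[flip]
  }

  nSig <- spec@nSignalGenes
  nCg <- spec@nContamGenes
  geneIds <- sprintf("gene%04d", seq_len(spec@nGenes))
  signalGenes <- if (nSig) geneIds[seq_len(nSig)] else character()
  contamGenes <- if (nCg) geneIds[nSig + seq_len(nCg)] else character()

  v <- matrix(stats::rnorm(spec@nGenes * n, 0, spec@noiseSd),
              spec@nGenes, n, dimnames = list(geneIds, ids))
  if (nSig) {
    rhoRes <- residualRho(spec@signalBlockRho, spec@effectDelta)
    f <- stats::rnorm(n)
    shared <- matrix(rep(sqrt(rhoRes) * f, each = nSig), nSig, n)
    shift <- matrix(rep(spec@effectDelta * s, each = nSig), nSig, n)
    v[seq_len(nSig), ] <- spec@noiseSd *
      (shift + shared + sqrt(1 - rhoRes) * v[seq_len(nSig), ] / spec@noiseSd)
  }
  if (nCg && nC)
    v[nSig + seq_len(nCg), cls == "contam"] <-
      v[nSig + seq_len(nCg), cls == "contam"] +
      spec@contamDelta * spec@noiseSd
  v <- v + spec@baselineMean

  cohort <- CohortTable(data.frame(
    sample_id = ids, time = time, event = event, stage = stage,
    adjuvant = FALSE, stringsAsFactors = FALSE))
  list(expression = ExpressionMatrix(v, scaleTag = "raw_log"),
       cohort = cohort,
       truth = list(signalGenes = signalGenes, contamGenes = contamGenes,
                    outliers = outliers,
                    class = stats::setNames(cls, ids)))
}

#' Write a synthetic cohort to disk in the formats the readers accept
#'
#' Expression as TSV ([readExpression()] layout), clinical records as CSV
#' ([readClinical()] default schema) and the ground truth as JSON.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.json"))
  writeExpression(cohort$expression, paths[["expression"]])
  writeClinical(cohort$cohort, paths[["clinical"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
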