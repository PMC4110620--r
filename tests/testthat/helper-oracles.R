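# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: pair counting by explicit double loop, likelihood
# maximisation by direct numerical optimisation of the binomial
# log-likelihood, the log-rank statistic from a hand-built risk table.

# Exhaustive cross-pair enumeration of the concordance AUC.
aucByEnumeration <- function(x1, x0, folded = TRUE) {
  credit <- 0
  for (a in x1) for (b in x0)
    credit <- credit + if (a > b) 1 else if (a == b) 0.5 else 0
  a <- credit / (length(x1) * length(x0))
  if (folded) max(a, 1 - a) else a
}

# LRT statistic via direct numerical maximisation of the binomial
# log-likelihood over (b0, b1), independent of glm/IRLS.
lrtByOptim <- function(x, y) {
  negll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(c(0, 0), negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  n1 <- sum(y); n0 <- sum(1 - y); n <- n1 + n0
  ll0 <- n1 * log(n1 / n) + n0 * log(n0 / n)
  2 * (-fit$value - ll0)
}

# Two-group log-rank chi-square from the observed-minus-expected risk
# table, built event time by event time.
logrankByTable <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- sort(unique(group))[1L]
  evTimes <- sort(unique(time[event]))
  O <- 0; E <- 0; V <- 0
  for (t in evTimes) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Hand product-limit table.
kmByHand <- function(time, event) {
  evTimes <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = numeric(), surv = numeric())
  for (t in evTimes) {
    n <- sum(time >= t)
    d <- sum(event & time == t)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Two-sample KS statistic as the max gap between ECDFs over pooled points.
ksByEcdf <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# Small labelled expression fixture: genes x cases matrix with the first
# nSignal genes shifted by delta in class 1.
makeToyExpression <- function(nGenes = 10, n1 = 8, n0 = 8, nSignal = 2,
                              delta = 2, seed = 1, baseline = 7) {
  set.seed(seed)
  n <- n1 + n0
  ids <- sprintf("s%02d", seq_len(n))
  v <- matrix(rnorm(nGenes * n, baseline), nGenes, n,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)), ids))
  if (nSignal > 0)
    v[seq_len(nSignal), seq_len(n1)] <- v[seq_len(nSignal), seq_len(n1)] + delta
  list(expr = ExpressionMatrix(v),
       cases = labelledCases(ids[seq_len(n1)], ids[(n1 + 1):n]))
}

# Minimal clinical cohort: k1 early deaths then k0 long survivors, with
# optional censoring among survivors and stages.
makeToyCohort <- function(nEarly = 10, nLate = 10, censorLate = 0,
                          stages = NULL) {
  n <- nEarly + nLate
  ids <- sprintf("s%02d", seq_len(n))
  time <- c(seq(2, 2 * nEarly, by = 2), seq(80, 80 + 4 * (nLate - 1), by = 4))
  lateEvent <- rep(TRUE, nLate)
  if (censorLate > 0)  # censored records spread across the survivor range
    lateEvent[unique(round(seq(1, nLate, length.out = censorLate)))] <- FALSE
  event <- c(rep(TRUE, nEarly), lateEvent)
  d <- data.frame(sample_id = ids, time = time, event = event,
                  stringsAsFactors = FALSE)
  if (!is.null(stages)) d$stage <- factor(stages, levels = c("I", "II", "III", "unknown"))
  CohortTable(d)
}
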