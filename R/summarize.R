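#' Bayes factor from posterior and prior probabilities
#'
#' Posterior odds divided by prior odds.  The reciprocal is the Bayes
#' factor "against" the hypothesis.  Probabilities of exactly 0 or 1 are
#' rejected with guidance (add a pseudo-sample or report a bound).
#'
#' @param posterior posterior probability, strictly inside (0, 1).
#' @param prior prior probability, strictly inside (0, 1).
#' @return named numeric: `for` and `against`.
#' @examples
#' bayesFactor(0.385, 0.5)  # ~0.63 for, ~1.6 against
#' @export
bayesFactor <- function(posterior, prior) {
  if (posterior <= 0 || posterior >= 1 || prior <= 0 || prior >= 1)
    stop("probabilities must lie strictly in (0, 1); for boundary ",
         "estimates from finite samples add a pseudo-sample ",
         "(see summarizeTraces) or report a bound")
  bf <- (posterior / (1 - posterior)) / (prior / (1 - prior))
  c("for" = bf, "against" = 1 / bf)
}

#' Prior probability for the most-similar pair of divergence times
#'
#' When two comparisons are singled out after seeing the posterior
#' (because their divergence times are the most similar), the appropriate
#' prior probability of their codivergence is the probability that the
#' two most similarly timed pairs share an event, which equals one minus
#' the prior probability that all n comparisons diverge independently.
#'
#' @param n number of comparisons (>= 2).
#' @param prior a [concentrationPrior()] or fixed alpha.
#' @param method,draws,seed passed to [probNumEventsMarginal()].
#' @return the corrected prior probability.
#' @examples
#' mostSimilarPairPrior(8, concentrationPrior(1.1, 56.1))  # ~0.5
#' @export
mostSimilarPairPrior <- function(n, prior, method = "quadrature",
                                 draws = 1e6, seed = 1) {
  stopifnot(n >= 2)
  1 - probNumEventsMarginal(n, n, prior, method = method, draws = draws,
                            seed = seed)
}

#' Model-choice summary of a trace set
#'
#' Pools the post-burn-in samples and computes the posterior probability
#' of each number of divergence events, Bayes factors comparing each k
#' against all other values (using the supplied prior P(k)), the pairwise
#' codivergence probability matrix, and posterior means with equal-tailed
#' 95% credible intervals for each comparison's divergence time.
#' Posterior probabilities of exactly 0 or 1 are corrected by one
#' pseudo-sample before forming odds and flagged in `bfBounded`.
#'
#' @param traces a `codivTraces` object from [runChains()].
#' @param priorK optional prior P(k) vector (k = 1..n); computed from the
#'   run's concentration prior by quadrature if omitted.
#' @param burnin optional burn-in override.
#' @param ciLevel credible-interval level (default 0.95).
#' @return a list of class `modelChoiceSummary`.
#' @export
summarizeTraces <- function(traces, priorK = NULL, burnin = NULL,
                            ciLevel = 0.95) {
  stopifnot(inherits(traces, "codivTraces"))
  post <- pooledSamples(traces, burnin)
  if (!nrow(post)) stop("no retained samples")
  n <- length(traces$labels)
  if (is.null(priorK))
    priorK <- probNumEventsMarginal(n, seq_len(n), traces$priors$alpha)
  N <- nrow(post)
  pk <- tabulate(post$k, nbins = n) / N
  bf <- rep(NA_real_, n)
  bfBounded <- logical(n)
  for (k in seq_len(n)) {
    pp <- pk[k]
    if (pp == 0 || pp == 1) {
      pp <- (pk[k] * N + (pp == 0)) / (N + 1)
      bfBounded[k] <- TRUE
    }
    if (priorK[k] > 0 && priorK[k] < 1)
      bf[k] <- unname(bayesFactor(pp, priorK[k])["for"])
  }
  evCols <- paste0("event_", traces$labels)
  co <- matrix(1, n, n, dimnames = list(traces$labels, traces$labels))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    co[i, j] <- co[j, i] <- mean(post[[evCols[i]]] == post[[evCols[j]]])
  }
  a <- (1 - ciLevel) / 2
  tauSummary <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- post[[paste0("time_", traces$labels[i])]]
    data.frame(comparison = traces$labels[i], postMean = mean(x),
               ciLower = unname(stats::quantile(x, a)),
               ciUpper = unname(stats::quantile(x, 1 - a)))
  }))
  structure(list(pk = pk, priorK = priorK, bayesFactors = bf,
                 bfBounded = bfBounded, coassignment = co,
                 tauSummary = tauSummary, nSamples = N),
            class = "modelChoiceSummary")
}

#' Randomly split a comparison's loci into two halves
#'
#' The loci are split uniformly at random into two subsets whose sizes
#' differ by at most one; both halves carry the same population map and
#' can be analysed downstream as two separate comparisons.  If the method
#' detects shared divergences reliably, the two halves -- which come from
#' the same pair of populations -- should be assigned to one event.
#'
#' @param data a [ComparisonData-class] object with >= 2 loci.
#' @param seed RNG seed for the split.
#' @return list of two [ComparisonData-class] objects (suffixes ".A",
#'   ".B").
#' @export
vetSplit <- function(data, seed = 1) {
  stopifnot(is(data, "ComparisonData"))
  nl <- length(data@loci)
  if (nl < 2) stop("need at least two loci to split")
  set.seed(seed)
  idx <- sample.int(nl)
  half <- ceiling(nl / 2)
  mk <- function(ids, suffix) {
    loci <- data@loci[ids]
    variable <- sum(vapply(loci, function(l) sum(l[, "r1"] + l[, "r2"] > 0), 0L))
    newComparisonData(paste0(data@label, suffix), data@populations,
                      data@sampleMap, loci, variable, 0L, 0L)
  }
  list(mk(sort(idx[seq_len(half)]), ".A"), mk(sort(idx[(half + 1):nl]), ".B"))
}

#' Nucleotide diversity within and between populations
#'
#' Mean per-site pairwise difference within each population (pi1, pi2) and
#' between populations (piBetween), computed from the per-site allele
#' counts.  Sites with fewer than two copies (within) or without a copy in
#' each population (between) are skipped; if no site qualifies the value
#' is NA with an attribute giving the reason.
#'
#' @param data a [ComparisonData-class] object.
#' @return named numeric: pi1, pi2, piBetween.
#' @export
nucleotideDiversity <- function(data) {
  stopifnot(is(data, "ComparisonData"))
  all <- do.call(rbind, data@loci)
  win <- function(n, r) {
    ok <- n >= 2
    if (!any(ok)) return(NA_real_)
    mean(2 * r[ok] * (n[ok] - r[ok]) / (n[ok] * (n[ok] - 1)))
  }
  n1 <- all[, "n1"]; n2 <- all[, "n2"]; r1 <- all[, "r1"]; r2 <- all[, "r2"]
  okb <- n1 >= 1 & n2 >= 1
  piB <- if (any(okb))
    mean((r1[okb] * (n2[okb] - r2[okb]) + (n1[okb] - r1[okb]) * r2[okb]) /
           (n1[okb] * n2[okb])) else NA_real_
  c(pi1 = win(n1, r1), pi2 = win(n2, r2), piBetween = piB)
}

#' Simulation performance report
#'
#' Aggregates a simulation study into the usual performance metrics:
#' root-mean-square error of the divergence-time estimates, coverage of
#' the 95% credible intervals, the confusion table of true versus
#' estimated numbers of events (estimated k = posterior mode, ties broken
#' toward smaller k), and the count of replicates whose worst PSRF exceeds
#' a threshold.
#'
#' @param tauTable data.frame with columns replicate, trueTau, postMean,
#'   ciLower, ciUpper (one row per replicate x comparison).
#' @param kTable data.frame with columns replicate, trueK, estK.
#' @param psrfValues optional numeric of per-replicate worst PSRF.
#' @param psrfThreshold flagging threshold (default 1.2).
#' @param nEvents number of possible event counts (defaults to max
#'   observed).
#' @return a list of class `performanceReport`: rmse, coverage, confusion,
#'   nFlagged.
#' @export
performanceReport <- function(tauTable, kTable, psrfValues = NULL,
                              psrfThreshold = 1.2, nEvents = NULL) {
  stopifnot(all(c("trueTau", "postMean", "ciLower", "ciUpper") %in%
                  names(tauTable)),
            all(c("trueK", "estK") %in% names(kTable)))
  rmse <- sqrt(mean((tauTable$postMean - tauTable$trueTau)^2))
  coverage <- mean(tauTable$trueTau >= tauTable$ciLower &
                     tauTable$trueTau <= tauTable$ciUpper)
  n <- if (is.null(nEvents)) max(kTable$trueK, kTable$estK) else nEvents
  confusion <- table(factor(kTable$trueK, levels = seq_len(n)),
                     factor(kTable$estK, levels = seq_len(n)),
                     dnn = c("true", "estimated"))
  nFlagged <- if (is.null(psrfValues)) NA_integer_ else
    sum(psrfValues > psrfThreshold, na.rm = TRUE)
  structure(list(rmse = rmse, coverage = coverage, confusion = confusion,
                 nFlagged = nFlagged, psrfThreshold = psrfThreshold),
            class = "performanceReport")
}

#' Posterior-mode number of events
#'
#' @param kSamples integer vector of sampled event counts.
#' @return the modal k; ties are broken toward smaller k.
#' @export
posteriorModeK <- function(kSamples) {
  tab <- tabulate(kSamples)
  which.max(tab)
}

#' Expected divergence-time gap from a mutation rate and a duration
#'
#' Converts a per-year mutation rate and a number of years into the
#' expected difference in divergence times on the substitutions-per-site
#' timescale (their product).  Used to ask whether two inferred divergence
#' times are distinguishable given how much island-separation times could
#' differ within one interglacial.
#'
#' @param rate substitutions per site per year (> 0 unless 0 is meant
#'   literally).
#' @param years number of years.
#' @return expected gap in substitutions per site.
#' @examples
#' expectedDivergenceGap(1.18e-9, 3000)  # ~3.5e-6
#' @export
expectedDivergenceGap <- function(rate, years) {
  if (rate < 0 || years < 0) stop("rate and years must be non-negative")
  rate * years
}

#' Write a model-choice summary as TSV and JSON
#'
#' @param summary a `modelChoiceSummary` from [summarizeTraces()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeModelChoiceSummary <- function(summary, dir) {
  stopifnot(inherits(summary, "modelChoiceSummary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nk <- file.path(dir, "num_events.tsv")
  utils::write.table(
    data.frame(k = seq_along(summary$pk), posterior = summary$pk,
               prior = summary$priorK, bayesFactor = summary$bayesFactors,
               bounded = summary$bfBounded),
    nk, sep = "\t", quote = FALSE, row.names = FALSE)
  tau <- file.path(dir, "divergence_times.tsv")
  utils::write.table(summary$tauSummary, tau, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "model_choice.json")
  jsonlite::write_json(
    list(pk = summary$pk, priorK = summary$priorK,
         bayesFactors = summary$bayesFactors,
         bfBounded = summary$bfBounded,
         coassignment = summary$coassignment,
         tauSummary = summary$tauSummary, nSamples = summary$nSamples),
    js, digits = NA)
  invisible(c(nk, tau, js))
}

#' Write a performance report as TSV and JSON
#'
#' @param report a `performanceReport` from [performanceReport()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writePerformanceReport <- function(report, dir) {
  stopifnot(inherits(report, "performanceReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "performance.tsv")
  utils::write.table(
    data.frame(rmse = report$rmse, coverage = report$coverage,
               nFlagged = report$nFlagged,
               psrfThreshold = report$psrfThreshold),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  conf <- file.path(dir, "confusion.tsv")
  utils::write.table(as.data.frame.matrix(report$confusion), conf,
                     sep = "\t", quote = FALSE, row.names = TRUE)
  js <- file.path(dir, "performance.json")
  jsonlite::write_json(
    list(rmse = report$rmse, coverage = report$coverage,
         confusion = matrix(as.numeric(report$confusion),
                            nrow(report$confusion),
                            dimnames = dimnames(report$confusion)),
         nFlagged = report$nFlagged),
    js, digits = NA)
  invisible(c(tsv, conf, js))
}
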