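#' @useDynLib codivtimes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Population map for one comparison
#'
#' Assigns every sequence identifier of a two-population comparison to one
#' of the two populations.
#'
#' @slot label single character; the comparison label.
#' @slot populations character of length two; the population labels.
#' @slot assignment named character; names are sequence identifiers, values
#'   are population labels.
#'
#' @exportClass PopulationMap
setClass("PopulationMap",
  representation(label = "character", populations = "character",
                 assignment = "character"))

setValidity("PopulationMap", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(object@populations) != 2L ||
      anyDuplicated(object@populations))
    msg <- c(msg, "exactly two distinct population labels are required")
  if (is.null(names(object@assignment)) || any(names(object@assignment) == ""))
    msg <- c(msg, "every sequence identifier must be named")
  if (anyDuplicated(names(object@assignment)))
    msg <- c(msg, "sequence identifiers must be unique")
  if (!all(object@assignment %in% object@populations))
    msg <- c(msg, "assignments must use the two population labels")
  if (!all(object@populations %in% object@assignment))
    msg <- c(msg, "each population needs at least one sequence")
  if (length(msg)) msg else TRUE
})

#' Construct a population map
#'
#' @param label comparison label.
#' @param populations character of length two naming the populations.
#' @param assignment named character vector mapping sequence identifiers to
#'   population labels.
#' @return a [PopulationMap-class] object.
#' @examples
#' populationMap("pairA", c("island1", "island2"),
#'               c(s1 = "island1", s2 = "island1", s3 = "island2"))
#' @export
populationMap <- function(label, populations, assignment) {
  new("PopulationMap", label = as.character(label),
      populations = as.character(populations),
      assignment = structure(as.character(assignment),
                             names = names(assignment)))
}

#' Compressed biallelic data for one pair of populations
#'
#' Holds the per-locus retained site patterns of one comparison after
#' binary recoding, the compressed (weighted) pattern table that enters the
#' likelihood, and the bookkeeping counts reported in dataset summaries.
#' Each element of `loci` is a numeric matrix with columns `n1`, `n2`
#' (sampled gene copies per population at the site) and `r1`, `r2` (copies
#' carrying state 1), one row per retained site.  Patterns are stored in a
#' canonical orientation (state 1 is the globally rarer state, ties broken
#' lexicographically), which the likelihood is invariant to.
#'
#' @slot label comparison label.
#' @slot populations the two population labels.
#' @slot sampleMap named character mapping sequence ids to populations.
#' @slot loci list of per-locus site-count matrices.
#' @slot patterns data.frame with columns n1, n2, r1, r2, weight.
#' @slot counts named numeric: loci, sites, variable, polyallelic,
#'   droppedEmpty.
#'
#' @exportClass ComparisonData
setClass("ComparisonData",
  representation(label = "character", populations = "character",
                 sampleMap = "character", loci = "list",
                 patterns = "data.frame", counts = "numeric"))

setValidity("ComparisonData", function(object) {
  msg <- character()
  cn <- c("loci", "sites", "variable", "polyallelic", "droppedEmpty")
  if (!all(cn %in% names(object@counts)))
    msg <- c(msg, "counts must contain loci/sites/variable/polyallelic/droppedEmpty")
  p <- object@patterns
  if (!all(c("n1", "n2", "r1", "r2", "weight") %in% names(p)))
    msg <- c(msg, "patterns must have columns n1, n2, r1, r2, weight")
  else {
    if (nrow(p) && any(p$r1 > p$n1 | p$r2 > p$n2 | p$r1 < 0 | p$r2 < 0))
      msg <- c(msg, "0 <= r <= n violated in pattern table")
    if (nrow(p) && any(p$n1 + p$n2 < 1))
      msg <- c(msg, "patterns need at least one sampled copy")
    if (nrow(p) && any(p$weight < 1))
      msg <- c(msg, "pattern weights must be >= 1")
    if (length(object@counts) &&
        !isTRUE(all.equal(sum(p$weight), unname(object@counts["sites"]))))
      msg <- c(msg, "pattern weights must sum to the retained site count")
  }
  if (length(msg)) msg else TRUE
})

#' Two-population divergence model parameters
#'
#' @slot tau divergence time, expected substitutions per site.
#' @slot theta1,theta2 descendant population-size parameters (Ne mu).
#' @slot rootMultiplier ratio of the ancestral size to the mean of theta1
#'   and theta2; thetaRoot = rootMultiplier * (theta1 + theta2) / 2.
#'
#' @exportClass PairModel
setClass("PairModel",
  representation(tau = "numeric", theta1 = "numeric", theta2 = "numeric",
                 rootMultiplier = "numeric"))

setValidity("PairModel", function(object) {
  msg <- character()
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (object@theta1 <= 0 || object@theta2 <= 0)
    msg <- c(msg, "theta1 and theta2 must be > 0")
  if (object@rootMultiplier <= 0) msg <- c(msg, "rootMultiplier must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a pair model
#'
#' @param tau divergence time (expected substitutions per site).
#' @param theta1,theta2 descendant population sizes (Ne mu).
#' @param rootMultiplier ancestral size relative to mean(theta1, theta2).
#' @return a [PairModel-class] object.
#' @export
pairModel <- function(tau, theta1, theta2, rootMultiplier = 1) {
  new("PairModel", tau = tau, theta1 = theta1, theta2 = theta2,
      rootMultiplier = rootMultiplier)
}

#' MCMC run settings
#'
#' @slot generations number of MCMC generations per chain.
#' @slot interval sampling interval (generations must be divisible by it).
#' @slot burnin number of samples discarded per chain, counting the initial
#'   state as the first sample.
#' @slot chains number of independent chains.
#' @slot seed master seed; per-chain seeds derive from it.
#'
#' @exportClass McmcSettings
setClass("McmcSettings",
  representation(generations = "integer", interval = "integer",
                 burnin = "integer", chains = "integer", seed = "integer"))

setValidity("McmcSettings", function(object) {
  msg <- character()
  if (object@generations < 1L) msg <- c(msg, "generations must be >= 1")
  if (object@interval < 1L || object@generations %% object@interval != 0L)
    msg <- c(msg, "generations must be divisible by the sampling interval")
  if (object@burnin < 0L) msg <- c(msg, "burnin must be >= 0")
  if (object@burnin >= object@generations %/% object@interval + 1L)
    msg <- c(msg, "burnin must leave at least one retained sample")
  if (object@chains < 1L) msg <- c(msg, "at least one chain is required")
  if (length(msg)) msg else TRUE
})

#' Construct MCMC settings
#'
#' @param generations generations per chain.
#' @param interval sampling interval.
#' @param burnin samples discarded per chain (the initial state counts as
#'   sample one).
#' @param chains number of independent chains.
#' @param seed master seed (integer).
#' @return an [McmcSettings-class] object.
#' @examples
#' mcmcSettings(150000, 100, burnin = 101, chains = 10, seed = 1)
#' @export
mcmcSettings <- function(generations, interval, burnin, chains = 1L, seed = 1L) {
  new("McmcSettings", generations = as.integer(generations),
      interval = as.integer(interval), burnin = as.integer(burnin),
      chains = as.integer(chains), seed = as.integer(seed))
}

#' Sampling skeleton of a multi-comparison dataset
#'
#' Records, for each comparison, the number of loci, the number of sites in
#' each locus and the number of gene copies sampled per population at every
#' site -- the three dimensions a template-matched simulation reproduces
#' exactly (including the patterns of missing data).
#'
#' @slot labels comparison labels.
#' @slot comparisons list (one per comparison) of lists (one per locus) of
#'   2 x sites integer matrices of per-site gene-copy counts.
#'
#' @exportClass SimulationTemplate
setClass("SimulationTemplate",
  representation(labels = "character", comparisons = "list"))

setValidity("SimulationTemplate", function(object) {
  if (length(object@labels) != length(object@comparisons))
    return("one label per comparison is required")
  for (cmp in object@comparisons) {
    if (!length(cmp)) return("each comparison needs at least one locus")
    for (loc in cmp) {
      if (!is.matrix(loc) || nrow(loc) != 2L || ncol(loc) < 1L)
        return("each locus must be a 2 x sites count matrix")
      if (any(loc < 0) || any(colSums(loc) < 1))
        return("every site needs at least one sampled gene copy")
    }
  }
  TRUE
})

#' @rdname ComparisonData-class
#' @param object a ComparisonData object.
#' @exportMethod show
setMethod("show", "ComparisonData", function(object) {
  cat("ComparisonData:", object@label, "\n")
  cat("  populations:", paste(object@populations, collapse = " / "), "\n")
  cat(sprintf("  %d loci, %d sites (%d variable, %d polyallelic)\n",
              object@counts["loci"], object@counts["sites"],
              object@counts["variable"], object@counts["polyallelic"]))
  cat(sprintf("  %d unique site patterns\n", nrow(object@patterns)))
})

setMethod("show", "PairModel", function(object) {
  cat(sprintf(
    "PairModel: tau=%.4g theta1=%.4g theta2=%.4g rootMultiplier=%.4g\n",
    object@tau, object@theta1, object@theta2, object@rootMultiplier))
})

setMethod("show", "McmcSettings", function(object) {
  cat(sprintf(
    "McmcSettings: %d generations, interval %d, burnin %d, %d chain(s), seed %d\n",
    object@generations, object@interval, object@burnin, object@chains,
    object@seed))
})

setMethod("show", "SimulationTemplate", function(object) {
  cat("SimulationTemplate with", length(object@labels), "comparison(s)\n")
  for (i in seq_along(object@labels)) {
    sites <- sum(vapply(object@comparisons[[i]], ncol, 0L))
    cat(sprintf("  %s: %d loci, %d sites\n", object@labels[i],
                length(object@comparisons[[i]]), sites))
  }
})

#' @rdname ComparisonData-class
#' @export
patternTable <- function(object) {
  stopifnot(is(object, "ComparisonData"))
  object@patterns
}

#' @rdname ComparisonData-class
#' @export
comparisonLabel <- function(object) {
  stopifnot(is(object, "ComparisonData") || is(object, "PopulationMap"))
  object@label
}

#' @rdname ComparisonData-class
#' @export
lociList <- function(object) {
  stopifnot(is(object, "ComparisonData"))
  object@loci
}
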