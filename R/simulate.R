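#' Extract the sampling skeleton of a dataset
#'
#' Records the three dimensions a template-matched simulation reproduces
#' exactly: the number of loci per comparison, the number of sites per
#' locus, and the number of gene copies sampled per population at each
#' site (i.e. the same patterns of missing data).
#'
#' @param datasets list of [ComparisonData-class] objects.
#' @return a [SimulationTemplate-class] object.
#' @export
extractTemplate <- function(datasets) {
  if (is(datasets, "ComparisonData")) datasets <- list(datasets)
  comps <- lapply(datasets, function(d) {
    stopifnot(is(d, "ComparisonData"))
    lapply(d@loci, function(l) {
      if (!nrow(l)) stop("cannot template a locus with no retained sites")
      m <- t(l[, c("n1", "n2"), drop = FALSE])
      rownames(m) <- c("n1", "n2")
      m
    })
  })
  new("SimulationTemplate",
      labels = vapply(datasets, function(d) d@label, ""),
      comparisons = comps)
}

#' Build a uniform template
#'
#' Convenience constructor for study designs with constant dimensions:
#' every comparison has `loci` loci of `sites` sites, with `copies1` and
#' `copies2` gene copies sampled at every site.
#'
#' @param labels comparison labels.
#' @param loci,sites,copies1,copies2 dimensions.
#' @return a [SimulationTemplate-class] object.
#' @export
uniformTemplate <- function(labels, loci, sites, copies1, copies2) {
  comps <- lapply(labels, function(l)
    replicate(loci, matrix(as.integer(c(copies1, copies2)), 2, sites,
                           dimnames = list(c("n1", "n2"), NULL)),
              simplify = FALSE))
  new("SimulationTemplate", labels = as.character(labels),
      comparisons = comps)
}

#' Serialise a template to JSON
#'
#' @param template a [SimulationTemplate-class] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTemplateJson <- function(template, path) {
  stopifnot(is(template, "SimulationTemplate"))
  x <- lapply(seq_along(template@labels), function(i)
    list(label = template@labels[i],
         loci = lapply(template@comparisons[[i]], function(m)
           list(n1 = as.integer(m[1, ]), n2 = as.integer(m[2, ])))))
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a template from JSON
#'
#' @param path JSON path written by [writeTemplateJson()].
#' @return a [SimulationTemplate-class] object.
#' @export
readTemplateJson <- function(path) {
  x <- jsonlite::read_json(path)
  comps <- lapply(x, function(cmp)
    lapply(cmp$loci, function(l)
      matrix(as.integer(c(unlist(l$n1), unlist(l$n2))), nrow = 2,
             byrow = TRUE, dimnames = list(c("n1", "n2"), NULL))))
  new("SimulationTemplate",
      labels = vapply(x, function(cmp) cmp$label, ""),
      comparisons = comps)
}

## simulate one locus: a structured-coalescent gene tree on the union of
## copies observed anywhere in the locus, then two-state characters at
## rate 1 along it for every site, with per-site missing copies masked.
simulateLocus <- function(copies, tau, th1, th2, thr) {
  n1u <- max(copies[1, ]); n2u <- max(copies[2, ])
  ntip <- n1u + n2u
  nsite <- ncol(copies)
  ## node numbering: tips 1..ntip (pop1 first), internals appended
  parent <- integer(2 * ntip); blen <- numeric(2 * ntip)
  nextNode <- ntip
  coalesce <- function(active, birth, theta, tmax, tnow) {
    while (length(active) > 1) {
      k <- length(active)
      w <- stats::rexp(1, rate = choose(k, 2) / (2 * theta))
      if (tnow + w > tmax) {
        tnow <- tmax
        break
      }
      tnow <- tnow + w
      pair <- sample.int(k, 2)
      nextNode <<- nextNode + 1L
      for (ch in active[pair]) {
        parent[ch] <<- nextNode
        blen[ch] <<- tnow - birth[ch]
      }
      birth[nextNode] <- tnow
      active <- c(active[-pair], nextNode)
    }
    list(active = active, birth = birth, tnow = tnow)
  }
  birth <- numeric(2 * ntip)
  a1 <- coalesce(seq_len(n1u), birth, th1, tau, 0)
  a2 <- coalesce(n1u + seq_len(n2u), a1$birth, th2, tau, 0)
  anc <- coalesce(c(a1$active, a2$active), a2$birth, thr, Inf, tau)
  root <- anc$active
  nnode <- nextNode
  ## close dangling branch lengths at the root
  states <- matrix(0L, nnode, nsite)
  states[root, ] <- stats::rbinom(nsite, 1, 0.5)
  ## evolve from root down: nodes were created in increasing time order,
  ## so descending index order is parent-before-child-safe reversed
  for (node in rev(seq_len(nnode))) {
    if (node == root) next
    p <- parent[node]
    if (p == 0L) next
    pd <- 0.5 * (1 - exp(-2 * blen[node]))
    flip <- stats::rbinom(nsite, 1, pd)
    states[node, ] <- bitwXor(states[p, ], flip)
  }
  ## per-site counts among unmasked copies (trailing copies are masked)
  sites <- matrix(0L, nsite, 4, dimnames = list(NULL, c("n1", "n2", "r1", "r2")))
  for (s in seq_len(nsite)) {
    n1 <- copies[1, s]; n2 <- copies[2, s]
    r1 <- if (n1 > 0) sum(states[seq_len(n1), s]) else 0L
    r2 <- if (n2 > 0) sum(states[n1u + seq_len(n2), s]) else 0L
    sites[s, ] <- canonicalizeSite(n1, n2, r1, r2)
  }
  sites
}

#' Draw a replicate divergence model from the priors
#'
#' @param ncomp number of comparisons.
#' @param priors a [divergencePriors()] object.
#' @return list: assign, times (per event), theta1, theta2,
#'   rootMultiplier (per comparison), alpha, k.
#' @export
drawDivergenceModel <- function(ncomp, priors) {
  stopifnot(inherits(priors, "divergencePriors"))
  alpha <- if (is.numeric(priors$alpha)) priors$alpha else
    stats::rgamma(1, shape = priors$alpha$shape, scale = priors$alpha$scale)
  assign <- canonicalPartition(samplePartition(ncomp, alpha))
  k <- max(assign)
  list(assign = assign,
       times = stats::rexp(k, rate = 1 / priors$tauMean),
       theta1 = stats::rgamma(ncomp, shape = priors$thetaShape,
                              scale = priors$thetaMean / priors$thetaShape),
       theta2 = stats::rgamma(ncomp, shape = priors$thetaShape,
                              scale = priors$thetaMean / priors$thetaShape),
       rootMultiplier = stats::rgamma(ncomp, shape = priors$multShape,
                                      scale = priors$multMean / priors$multShape),
       alpha = alpha, k = k)
}

#' Simulate a template-matched replicate
#'
#' Draws a divergence model from the priors (partition from the Dirichlet
#' process with alpha from its hyperprior, event times from the
#' exponential tau prior, sizes from their gamma priors), then simulates
#' data that exactly match the template: one structured-coalescent gene
#' tree per locus on the union of copies observed anywhere in the locus
#' (all sites of a locus share that tree; no intralocus recombination),
#' two-state characters evolved at rate 1 for every site, and per-site
#' missingness realised by masking absent copies.  With `snpOnly = TRUE`
#' at most the first variable site of each locus is retained.
#'
#' @param template a [SimulationTemplate-class] object.
#' @param priors a [divergencePriors()] object.
#' @param seed RNG seed for the replicate.
#' @param snpOnly keep at most one variable site per locus.
#' @return list of class `simulatedReplicate`: `truth` (the drawn model),
#'   `data` (list of [ComparisonData-class]), `seed`.
#' @export
simulateReplicate <- function(template, priors, seed, snpOnly = FALSE) {
  stopifnot(is(template, "SimulationTemplate"))
  set.seed(seed)
  ncomp <- length(template@labels)
  truth <- drawDivergenceModel(ncomp, priors)
  data <- vector("list", ncomp)
  for (i in seq_len(ncomp)) {
    tau <- truth$times[truth$assign[i]]
    th1 <- truth$theta1[i]; th2 <- truth$theta2[i]
    thr <- truth$rootMultiplier[i] * (th1 + th2) / 2
    loci <- lapply(template@comparisons[[i]], function(copies) {
      if (all(colSums(copies) < 1)) stop("template locus with no sampled copies")
      simulateLocus(copies, tau, th1, th2, thr)
    })
    variable <- sum(vapply(loci, function(l) sum(l[, "r1"] + l[, "r2"] > 0), 0L))
    cd <- newComparisonData(
      label = template@labels[i],
      populations = c("pop1", "pop2"),
      sampleMap = structure(c("pop1", "pop2"),
                            names = paste0(template@labels[i], c("_p1", "_p2"))),
      loci = loci, variable = variable, polyallelic = 0L, droppedEmpty = 0L)
    data[[i]] <- if (snpOnly) snpFilter(cd) else cd
  }
  structure(list(truth = truth, data = data, seed = seed),
            class = "simulatedReplicate")
}

#' Keep at most one variable site per locus
#'
#' Retains the first variable site (in locus order) of every locus and
#' drops all other sites; loci without a variable site contribute nothing.
#' Warns if no variable sites exist at all.
#'
#' @param data a [ComparisonData-class] object.
#' @return a filtered [ComparisonData-class] object.
#' @export
snpFilter <- function(data) {
  stopifnot(is(data, "ComparisonData"))
  loci <- lapply(data@loci, function(l) {
    v <- which(l[, "r1"] + l[, "r2"] > 0)
    l[v[1], , drop = FALSE][seq_len(length(v) > 0), , drop = FALSE]
  })
  loci <- loci[vapply(loci, nrow, 0L) > 0]
  if (!length(loci)) {
    warning("no variable sites; SNP-filtered dataset is empty")
    return(newComparisonData(data@label, data@populations, data@sampleMap,
                             list(), 0L, 0L, 0L))
  }
  newComparisonData(data@label, data@populations, data@sampleMap, loci,
                    variable = length(loci), polyallelic = 0L,
                    droppedEmpty = 0L)
}

#' Write a replicate's truth table
#'
#' @param replicates list of `simulatedReplicate` objects.
#' @param path output TSV.
#' @return the truth data.frame, invisibly.
#' @export
writeTruthTable <- function(replicates, path) {
  rows <- lapply(seq_along(replicates), function(i) {
    r <- replicates[[i]]
    ncomp <- length(r$truth$assign)
    data.frame(replicate = i, seed = r$seed,
               comparison = vapply(r$data, function(d) d@label, ""),
               event = r$truth$assign,
               trueTau = r$truth$times[r$truth$assign],
               theta1 = r$truth$theta1, theta2 = r$truth$theta2,
               rootMultiplier = r$truth$rootMultiplier,
               alpha = r$truth$alpha, trueK = r$truth$k)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
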