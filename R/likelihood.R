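#' Two-state transition probability
#'
#' Probability that a lineage is in the same character state after time
#' `t` under the symmetric two-state substitution process scaled to one
#' expected substitution per unit time: (1 + exp(-2 t)) / 2.  Stationary
#' frequencies are (1/2, 1/2), the binary analogue of Jukes-Cantor.
#'
#' @param t time in expected substitutions per site (vectorised).
#' @return probability of observing the same state.
#' @examples
#' transitionProbSame(0)          # 1
#' transitionProbSame(log(2) / 2) # 0.75
#' @export
transitionProbSame <- function(t) {
  if (any(t < 0)) stop("time must be non-negative")
  0.5 * (1 + exp(-2 * t))
}

#' State space of the lineage-ancestry process
#'
#' The likelihood tracks a site's history on the triangular state space
#' (m, j): m surviving ancestral lineages (1..n), j of them carrying state
#' 1 (0..m).  States are ordered (1,0), (1,1), (2,0), ..., (n,n).
#'
#' @param n number of sampled gene copies.
#' @return a two-column integer matrix of (m, j) pairs.
#' @export
branchStateSpace <- function(n) {
  stopifnot(n >= 1)
  do.call(rbind, lapply(seq_len(n), function(m) cbind(m = m, j = 0:m)))
}

#' Propagate a branch partial likelihood
#'
#' Applies the joint coalescent-mutation generator to a count-space
#' partial-likelihood vector for time `length` along a branch with
#' population-size parameter `theta`.  A pair of gene copies coalesces at
#' rate 1/(2 theta) and each lineage flips state at rate 1.  With
#' `length = Inf` (the ancestral root branch) the fully coalesced
#' contribution is returned, with the surviving lineage's state weighted by
#' the (1/2, 1/2) stationary distribution.
#'
#' @param partial numeric vector over [branchStateSpace()] of length
#'   n (n + 3) / 2.
#' @param n number of sampled gene copies the space was built for.
#' @param length branch length in expected substitutions per site; may be
#'   `Inf`.
#' @param theta population-size parameter (Ne mu), > 0.
#' @return the propagated partial vector.
#' @export
propagateBranch <- function(partial, n, length, theta) {
  as.vector(.propagateBranchCpp(as.numeric(partial), as.integer(n), length,
                                theta))
}

#' Probabilities of all count patterns for one pair model
#'
#' Computes the matrix of probabilities of observing r1 of n1 copies in
#' state 1 in population 1 and r2 of n2 in population 2, for all (r1, r2),
#' under a two-population divergence model.  Rows index r1 = 0..n1, columns
#' r2 = 0..n2; the entries sum to one.  The likelihood is not conditioned
#' on the site being variable.
#'
#' @param n1,n2 sampled gene copies per population (n2 = 0 allowed for
#'   sites with data from one population only).
#' @param model a [PairModel-class] object.
#' @return numeric matrix (n1 + 1) x (n2 + 1) of pattern probabilities.
#' @examples
#' m <- pairModel(tau = 0.002, theta1 = 0.004, theta2 = 0.004)
#' sum(pairPatternProbs(2, 2, m))  # 1
#' @export
pairPatternProbs <- function(n1, n2, model) {
  stopifnot(is(model, "PairModel"))
  thr <- model@rootMultiplier * (model@theta1 + model@theta2) / 2
  .pairPatternProbsCpp(as.integer(n1), as.integer(n2), model@tau,
                       model@theta1, model@theta2, thr)
}

#' Log-likelihood of one site pattern
#'
#' @param n1,n2 sampled gene copies per population.
#' @param r1,r2 copies carrying state 1.
#' @param model a [PairModel-class] object.
#' @return log probability of the count pattern.
#' @export
patternLogLikelihood <- function(n1, n2, r1, r2, model) {
  if (n1 + n2 < 1) stop("pattern has no sampled gene copies")
  if (r1 < 0 || r1 > n1 || r2 < 0 || r2 > n2) stop("0 <= r <= n violated")
  P <- pairPatternProbs(n1, n2, model)
  log(P[r1 + 1, r2 + 1])
}

#' Log-likelihood of a comparison
#'
#' Weighted sum of pattern log-likelihoods over the compressed pattern
#' table of a comparison.
#'
#' @param data a [ComparisonData-class] object, or a data.frame/matrix with
#'   columns n1, n2, r1, r2, weight.
#' @param model a [PairModel-class] object.
#' @return the log-likelihood.
#' @export
comparisonLogLikelihood <- function(data, model) {
  stopifnot(is(model, "PairModel"))
  pat <- if (is(data, "ComparisonData")) data@patterns else as.data.frame(data)
  if (!nrow(pat)) stop("empty pattern table")
  m <- as.matrix(pat[, c("n1", "n2", "r1", "r2", "weight")])
  .comparisonLogLikCpp(m, model@tau, model@theta1, model@theta2,
                       model@rootMultiplier)
}

#' Monte-Carlo oracle for a pattern probability
#'
#' Independent check of the analytic likelihood: simulates gene trees under
#' the structured coalescent for the pair (two populations of sizes theta1
#' and theta2 merging at tau into an ancestor of size thetaRoot), computes
#' the pattern probability on each tree by pruning under the symmetric
#' two-state model, and averages.  Returns the count-pattern probability
#' estimate with its Monte-Carlo standard error.
#'
#' @param n1,n2,r1,r2 the count pattern.
#' @param model a [PairModel-class] object.
#' @param replicates number of simulated gene trees (>= 1000).
#' @param seed RNG seed.
#' @return named numeric: `mean` and `se`.
#' @export
mcOracleLogLikelihood <- function(n1, n2, r1, r2, model, replicates = 10000,
                                  seed = 1) {
  stopifnot(is(model, "PairModel"), replicates >= 1000)
  if (n1 + n2 < 1) stop("pattern has no sampled gene copies")
  set.seed(seed)
  thr <- model@rootMultiplier * (model@theta1 + model@theta2) / 2
  evolve <- function(p, t) {
    ps <- transitionProbSame(t)
    cbind(ps * p[, 1] + (1 - ps) * p[, 2], (1 - ps) * p[, 1] + ps * p[, 2])
  }
  ## partial likelihood pruning over one simulated history; partials held
  ## as rows of a matrix (columns = state 0, state 1)
  simPop <- function(partials, theta, tmax) {
    t <- 0
    while (nrow(partials) > 1) {
      k <- nrow(partials)
      w <- stats::rexp(1, rate = choose(k, 2) / (2 * theta))
      if (t + w > tmax) {
        return(evolve(partials, tmax - t))
      }
      t <- t + w
      partials <- evolve(partials, w)
      pair <- sample.int(k, 2)
      merged <- partials[pair[1], ] * partials[pair[2], ]
      partials <- rbind(partials[-pair, , drop = FALSE], merged)
    }
    if (is.finite(tmax)) evolve(partials, tmax - t) else partials
  }
  tip <- function(n, r) {
    if (n == 0) return(matrix(numeric(0), ncol = 2))
    rbind(matrix(rep(c(0, 1), each = r), ncol = 2),
          matrix(rep(c(1, 0), each = n - r), ncol = 2))
  }
  probs <- vapply(seq_len(replicates), function(i) {
    a1 <- simPop(tip(n1, r1), model@theta1, model@tau)
    a2 <- simPop(tip(n2, r2), model@theta2, model@tau)
    anc <- simPop(rbind(a1, a2), thr, Inf)
    sum(0.5 * anc[1, ])
  }, 0)
  cnt <- choose(n1, r1) * choose(n2, r2)
  c(mean = mean(probs) * cnt, se = stats::sd(probs) / sqrt(replicates) * cnt)
}
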