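#' Number of possible divergence models
#'
#' The number of ways to partition `n` comparisons into divergence events
#' is the Bell number B(n), computed via the Bell triangle.  Eight
#' comparisons admit 4140 divergence models.
#'
#' @param n number of comparisons (1..12).
#' @return the Bell number B(n).
#' @examples
#' countPartitions(8)  # 4140
#' @export
countPartitions <- function(n) {
  if (n < 1 || n > 12 || n != round(n)) stop("n must be an integer in 1..12")
  row <- 1
  if (n == 1) return(1)
  for (i in 2:n) {
    nr <- numeric(i)
    nr[1] <- row[i - 1]
    for (j in 2:i) nr[j] <- nr[j - 1] + row[j - 1]
    row <- nr
  }
  row[n]
}

## canonical form: events numbered by first appearance
canonicalPartition <- function(assign) {
  u <- unique(assign)
  match(assign, u)
}

#' Dirichlet-process (CRP) probability of a partition
#'
#' Probability of a set partition of n items under the Chinese restaurant
#' process with concentration alpha:
#' alpha^k * prod((size_i - 1)!) / prod_{i=0}^{n-1}(alpha + i).
#'
#' @param assign integer vector assigning each comparison to an event;
#'   canonicalised internally by first appearance.
#' @param alpha concentration parameter, > 0.
#' @return the partition probability.
#' @examples
#' crpPartitionProb(c(1, 1), 1)  # 1/2
#' @export
crpPartitionProb <- function(assign, alpha) {
  stopifnot(alpha > 0)
  assign <- canonicalPartition(assign)
  n <- length(assign)
  sizes <- tabulate(assign)
  k <- length(sizes)
  exp(k * log(alpha) + sum(lfactorial(sizes - 1)) -
        sum(log(alpha + 0:(n - 1))))
}

stirling1Unsigned <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (i in 1:n)
    for (k in 1:i)
      s[i + 1, k + 1] <- s[i, k] + (i - 1) * s[i, k + 1]
  s
}

#' Prior probability of k divergence events given alpha
#'
#' P(k | n, alpha) = |s(n, k)| alpha^k / alpha^{(n)}, with unsigned
#' Stirling numbers of the first kind and rising factorial alpha^{(n)}.
#'
#' @param n number of comparisons.
#' @param k number of events (vectorised, 1..n).
#' @param alpha concentration parameter.
#' @return probability (vector).
#' @export
probNumEventsGivenAlpha <- function(n, k, alpha) {
  stopifnot(n >= 1, all(k >= 1), all(k <= n), alpha > 0)
  s <- stirling1Unsigned(n)
  lrise <- sum(log(alpha + 0:(n - 1)))
  exp(log(s[n + 1, k + 1]) + k * log(alpha) - lrise)
}

#' Gamma hyperprior on the concentration parameter
#'
#' @param shape,scale gamma (shape, scale) parameters, both > 0.  The mean
#'   is shape * scale.
#' @return a list of class `concentrationPrior`.
#' @examples
#' concentrationPrior(1.1, 56.1)  # places ~half the prior mass on k = n
#' @export
concentrationPrior <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale), class = "concentrationPrior")
}

#' Marginal prior probability of k events under a gamma hyperprior
#'
#' Marginalises P(k | n, alpha) over alpha ~ Gamma(shape, scale), either by
#' adaptive quadrature or by Monte-Carlo averaging of the exact
#' conditional over alpha draws.
#'
#' @param n number of comparisons.
#' @param k number of events (vectorised).
#' @param prior a [concentrationPrior()] (or a single fixed alpha value,
#'   which reduces to [probNumEventsGivenAlpha()]).
#' @param method "quadrature" or "monte-carlo".
#' @param draws Monte-Carlo draws (default 1e6, used when
#'   method = "monte-carlo").
#' @param seed RNG seed for the Monte-Carlo method.
#' @return probability (vector over k).
#' @examples
#' probNumEventsMarginal(8, 8, concentrationPrior(1.1, 56.1))  # ~0.5
#' @export
probNumEventsMarginal <- function(n, k, prior, method = c("quadrature", "monte-carlo"),
                                  draws = 1e6, seed = 1) {
  method <- match.arg(method)
  if (is.numeric(prior) && length(prior) == 1)
    return(probNumEventsGivenAlpha(n, k, prior))
  stopifnot(inherits(prior, "concentrationPrior"))
  if (method == "quadrature") {
    vapply(k, function(kk) {
      stats::integrate(function(a)
        vapply(a, function(x) probNumEventsGivenAlpha(n, kk, x), 0) *
          stats::dgamma(a, shape = prior$shape, scale = prior$scale),
        0, Inf, rel.tol = 1e-8)$value
    }, 0)
  } else {
    set.seed(seed)
    a <- stats::rgamma(draws, shape = prior$shape, scale = prior$scale)
    s <- stirling1Unsigned(n)
    lrise <- rowSums(log(outer(a, 0:(n - 1), `+`)))
    vapply(k, function(kk)
      mean(exp(log(s[n + 1, kk + 1]) + kk * log(a) - lrise)), 0)
  }
}

#' Prior mean number of divergence events
#'
#' E(k | n, alpha) = sum_{i=0}^{n-1} alpha / (alpha + i).  At n = 8 and
#' alpha = 4.695 (the mean of a Gamma(1.5, 3.13) hyperprior) this is ~5.
#'
#' @param n number of comparisons.
#' @param alpha concentration parameter.
#' @return the expected number of events.
#' @export
expectedNumEvents <- function(n, alpha) {
  stopifnot(n >= 1, alpha > 0)
  sum(alpha / (alpha + 0:(n - 1)))
}

#' Prior probability that two specific comparisons share an event
#'
#' Under the Dirichlet process two given comparisons fall in the same
#' event with probability 1 / (1 + alpha), independent of n.  With a gamma
#' hyperprior the marginal E[1 / (1 + alpha)] is returned, by quadrature or
#' Monte-Carlo.
#'
#' @param prior a [concentrationPrior()] or a fixed alpha.
#' @param method "quadrature" or "monte-carlo".
#' @param draws Monte-Carlo draws.
#' @param seed RNG seed for Monte-Carlo.
#' @return the pairwise co-assignment prior probability.
#' @examples
#' probPairShared(1)                            # 1/2
#' probPairShared(concentrationPrior(1.5, 3.13))  # ~0.265
#' @export
probPairShared <- function(prior, method = c("quadrature", "monte-carlo"),
                           draws = 1e6, seed = 1) {
  method <- match.arg(method)
  if (is.numeric(prior) && length(prior) == 1) {
    stopifnot(prior > 0)
    return(1 / (1 + prior))
  }
  stopifnot(inherits(prior, "concentrationPrior"))
  if (method == "quadrature") {
    stats::integrate(function(a)
      1 / (1 + a) * stats::dgamma(a, shape = prior$shape, scale = prior$scale),
      0, Inf, rel.tol = 1e-10)$value
  } else {
    set.seed(seed)
    mean(1 / (1 + stats::rgamma(draws, shape = prior$shape,
                                scale = prior$scale)))
  }
}

#' Draw a partition from the Dirichlet process
#'
#' Sequential CRP draw; with a gamma hyperprior alpha is drawn first.
#'
#' @param n number of comparisons.
#' @param prior fixed alpha or a [concentrationPrior()].
#' @param seed optional RNG seed (uses the current RNG state if NULL).
#' @return integer assignment vector in canonical (first-appearance) order.
#' @export
samplePartition <- function(n, prior, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- if (inherits(prior, "concentrationPrior"))
    stats::rgamma(1, shape = prior$shape, scale = prior$scale) else prior
  stopifnot(alpha > 0)
  assign <- integer(n)
  assign[1] <- 1L
  k <- 1L
  if (n > 1) for (i in 2:n) {
    sizes <- tabulate(assign[1:(i - 1)], nbins = k)
    p <- c(sizes, alpha)
    pick <- sample.int(k + 1L, 1L, prob = p)
    if (pick > k) k <- k + 1L
    assign[i] <- pick
  }
  assign
}
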