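#' Priors for the joint divergence model
#'
#' Bundles the priors of the full model: exponential prior on divergence
#' times, gamma (shape, mean) priors on the descendant population sizes
#' and on the root-size multiplier, and the gamma (shape, scale) hyperprior
#' on the Dirichlet-process concentration (or a fixed alpha).
#'
#' @param tauMean mean of the exponential divergence-time prior
#'   (substitutions per site).
#' @param thetaShape,thetaMean gamma prior on theta1 and theta2.
#' @param multShape,multMean gamma prior on the root-size multiplier.
#' @param alpha a [concentrationPrior()] or a fixed numeric alpha.
#' @return a list of class `divergencePriors`.
#' @examples
#' divergencePriors(tauMean = 0.005, alpha = concentrationPrior(1.1, 56.1))
#' @export
divergencePriors <- function(tauMean = 0.005, thetaShape = 4,
                             thetaMean = 0.004, multShape = 100,
                             multMean = 1,
                             alpha = concentrationPrior(1.1, 56.1)) {
  stopifnot(tauMean > 0, thetaShape > 0, thetaMean > 0, multShape > 0,
            multMean > 0)
  if (is.numeric(alpha)) stopifnot(length(alpha) == 1, alpha > 0)
  else stopifnot(inherits(alpha, "concentrationPrior"))
  structure(list(tauMean = tauMean, thetaShape = thetaShape,
                 thetaMean = thetaMean, multShape = multShape,
                 multMean = multMean, alpha = alpha),
            class = "divergencePriors")
}

priorsForCpp <- function(priors) {
  fixed <- is.numeric(priors$alpha)
  list(tauMean = priors$tauMean, thetaShape = priors$thetaShape,
       thetaMean = priors$thetaMean, multShape = priors$multShape,
       multMean = priors$multMean,
       alphaFixed = fixed,
       alphaShape = if (fixed) 1 else priors$alpha$shape,
       alphaScale = if (fixed) 1 else priors$alpha$scale)
}

#' Retained-sample bookkeeping
#'
#' Samples per chain are generations / interval + 1 (the initial state is
#' recorded) minus the burn-in, which counts the initial state as the
#' first sample.  150,000 generations sampled every 100th with burn-in 101
#' and 10 chains retain 1400 samples per chain, 14,000 in total.
#'
#' @param settings an [McmcSettings-class] object.
#' @return named numeric: `perChain` and `total`.
#' @examples
#' retainedSamples(mcmcSettings(150000, 100, 101, chains = 10))
#' @export
retainedSamples <- function(settings) {
  stopifnot(is(settings, "McmcSettings"))
  per <- settings@generations %/% settings@interval + 1L - settings@burnin
  c(perChain = per, total = per * settings@chains)
}

drawInitialState <- function(ncomp, priors) {
  alpha <- if (is.numeric(priors$alpha)) priors$alpha else
    stats::rgamma(1, shape = priors$alpha$shape, scale = priors$alpha$scale)
  assign <- canonicalPartition(samplePartition(ncomp, alpha))
  k <- max(assign)
  list(assign = as.integer(assign - 1L),
       times = stats::rexp(k, rate = 1 / priors$tauMean),
       theta1 = stats::rgamma(ncomp, shape = priors$thetaShape,
                              scale = priors$thetaMean / priors$thetaShape),
       theta2 = stats::rgamma(ncomp, shape = priors$thetaShape,
                              scale = priors$thetaMean / priors$thetaShape),
       rootMultiplier = stats::rgamma(ncomp, shape = priors$multShape,
                                      scale = priors$multMean / priors$multShape),
       alpha = alpha)
}

defaultControl <- function(priorOnly = FALSE) {
  list(priorOnly = priorOnly, updateTau = TRUE, updateThetas = TRUE,
       updateMult = TRUE, updatePartition = TRUE, updateAlpha = TRUE,
       scaleTau = 0.5, scaleTheta = 0.4, scaleMult = 0.3)
}

traceColumnNames <- function(labels) {
  c("generation", "ln_likelihood", "alpha", "k",
    as.vector(vapply(labels, function(l)
      paste0(c("event_", "time_", "theta1_", "theta2_", "rootmult_"), l),
      character(5))))
}

#' Run MCMC chains
#'
#' Samples the joint posterior of the divergence-event partition, the
#' event times, the per-comparison demographic parameters and the
#' concentration parameter for a set of comparisons.  Per-chain seeds are
#' derived deterministically from the master seed, initial states are drawn
#' from the priors, and each chain's full sample path (including the
#' initial state) is returned; burn-in is applied later, at summary time.
#'
#' @param data list of [ComparisonData-class] objects (or pattern
#'   data.frames with columns n1, n2, r1, r2, weight).
#' @param priors a [divergencePriors()] object.
#' @param settings an [McmcSettings-class] object.
#' @param control list of update flags and proposal scales; see
#'   `defaultControl` in the sources.  `priorOnly = TRUE` disables the
#'   likelihood (useful for validating prior recovery).
#' @param init optional initial state (a list with assign, times, theta1,
#'   theta2, rootMultiplier, alpha), used for every chain instead of a
#'   prior draw; needed when conditioning on fixed parameter values.
#' @param outputDir if non-NULL, one trace TSV per chain is written there.
#' @return a list of class `codivTraces`: `chains` (list of data.frames),
#'   `labels`, `settings`, `priors`, `acceptance`.
#' @export
runChains <- function(data, priors, settings, control = list(), init = NULL,
                      outputDir = NULL) {
  stopifnot(is(settings, "McmcSettings"), inherits(priors, "divergencePriors"))
  if (!length(data)) stop("at least one comparison is required")
  ctrl <- utils::modifyList(defaultControl(), control)
  labels <- vapply(seq_along(data), function(i) {
    d <- data[[i]]
    if (is(d, "ComparisonData")) d@label else
      if (!is.null(names(data)[i]) && nzchar(names(data)[i])) names(data)[i]
      else paste0("comparison", i)
  }, "")
  tables <- lapply(data, function(d) {
    p <- if (is(d, "ComparisonData")) d@patterns else as.data.frame(d)
    if (!nrow(p)) stop("empty pattern table")
    as.matrix(p[, c("n1", "n2", "r1", "r2", "weight")])
  })
  chains <- vector("list", settings@chains)
  acc <- vector("list", settings@chains)
  cols <- traceColumnNames(labels)
  for (ch in seq_len(settings@chains)) {
    set.seed((settings@seed + 7919L * (ch - 1L)) %% .Machine$integer.max)
    state <- if (is.null(init)) drawInitialState(length(data), priors) else init
    res <- .runChainCpp(tables, priorsForCpp(priors), state,
                        settings@generations, settings@interval, ctrl)
    df <- as.data.frame(res$samples)
    names(df) <- cols
    df$chain <- ch
    chains[[ch]] <- df
    acc[[ch]] <- res$acceptance
    if (!is.null(outputDir)) {
      if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
      utils::write.table(df, file.path(outputDir, sprintf("chain%02d.tsv", ch)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  structure(list(chains = chains, labels = labels, settings = settings,
                 priors = priors, acceptance = acc),
            class = "codivTraces")
}

#' Pool retained samples across chains
#'
#' Drops the burn-in samples of each chain (the initial state counts as
#' sample one) and row-binds the remainder.
#'
#' @param traces a `codivTraces` object from [runChains()].
#' @param burnin overrides the burn-in in the run settings if given.
#' @return a data.frame of pooled post-burn-in samples.
#' @export
pooledSamples <- function(traces, burnin = NULL) {
  stopifnot(inherits(traces, "codivTraces"))
  b <- if (is.null(burnin)) traces$settings@burnin else as.integer(burnin)
  do.call(rbind, lapply(traces$chains, function(df) {
    if (b >= nrow(df)) stop("burn-in leaves no samples")
    df[(b + 1):nrow(df), , drop = FALSE]
  }))
}

#' Potential scale reduction factor
#'
#' Multi-chain PSRF: the square root of the weighted ratio of the pooled
#' posterior-variance estimate to the mean within-chain variance
#' (Brooks-Gelman form).  Values near 1 indicate convergence; analyses in
#' this package flag values above 1.005 (empirical runs) or 1.2
#' (simulation screening).
#'
#' @param chains list of numeric vectors, one per chain (equal lengths).
#' @return the PSRF.
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("PSRF needs at least two chains")
  n <- unique(vapply(chains, length, 0L))
  if (length(n) != 1 || n < 10) stop("chains must share a length of >= 10")
  m <- length(chains)
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, stats::var, 0))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  varplus <- (n - 1) / n * W + B / n
  sqrt((m + 1) / m * varplus / W - (n - 1) / (m * n))
}

#' Effective sample size
#'
#' Autocorrelation-adjusted effective sample size of a scalar MCMC trace,
#' using the sum of autocorrelations with Geyer's initial monotone
#' positive-sequence truncation.  A constant trace returns 0 with a
#' warning.
#'
#' @param x numeric vector of samples (>= 100).
#' @return the effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 100) stop("ESS needs at least 100 samples")
  if (stats::var(x) == 0) {
    warning("constant trace; ESS is 0")
    return(0)
  }
  maxlag <- min(n - 1, 2000)
  rho <- as.vector(stats::acf(x, lag.max = maxlag, plot = FALSE,
                              demean = TRUE)$acf)
  ## Geyer: Gamma_m = rho_{2m} + rho_{2m+1}, keep while positive, enforce
  ## monotone non-increasing
  npair <- (maxlag + 1) %/% 2
  gam <- numeric(npair)
  for (i in seq_len(npair)) {
    g <- rho[2 * i - 1] + if (2 * i <= maxlag + 1) rho[2 * i] else 0
    gam[i] <- g
  }
  keep <- which(gam <= 0)
  upto <- if (length(keep)) keep[1] - 1 else npair
  if (upto < 1) upto <- 1
  gam <- gam[seq_len(upto)]
  gam <- cummin(gam)
  tau <- max(2 * sum(gam) - 1, 1)
  min(n / tau, n)
}

#' Convergence diagnostics for a trace set
#'
#' PSRF and ESS for every scalar column of the trace (log-likelihood,
#' alpha, event times and demographic parameters), computed after burn-in.
#'
#' @param traces a `codivTraces` object.
#' @param burnin optional burn-in override.
#' @return data.frame with columns quantity, psrf, ess.
#' @export
traceDiagnostics <- function(traces, burnin = NULL) {
  stopifnot(inherits(traces, "codivTraces"))
  b <- if (is.null(burnin)) traces$settings@burnin else as.integer(burnin)
  keepCols <- setdiff(names(traces$chains[[1]]),
                      c("generation", "chain",
                        grep("^event_", names(traces$chains[[1]]), value = TRUE)))
  post <- lapply(traces$chains, function(df) df[(b + 1):nrow(df), , drop = FALSE])
  out <- lapply(keepCols, function(cn) {
    per <- lapply(post, `[[`, cn)
    pooled <- unlist(per)
    data.frame(quantity = cn,
               psrf = if (length(per) >= 2 && stats::var(pooled) > 0)
                 psrf(per) else NA_real_,
               ess = if (stats::var(pooled) == 0) 0 else
                 if (length(pooled) >= 100) ess(pooled) else NA_real_)
  })
  do.call(rbind, out)
}
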