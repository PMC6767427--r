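test_that("retained-sample bookkeeping matches the run designs", {
  expect_equal(retainedSamples(mcmcSettings(150000, 100, 101, chains = 10)),
               c(perChain = 1400, total = 14000))
  expect_equal(retainedSamples(mcmcSettings(150000, 100, 501, chains = 4)),
               c(perChain = 1000, total = 4000))
  expect_equal(unname(retainedSamples(mcmcSettings(10, 1, 0))["perChain"]), 11)
  expect_error(mcmcSettings(100, 3, 0), "divisible")
  expect_error(mcmcSettings(100, 10, 50), "retained")
})

test_that("PSRF distinguishes mixed from unmixed chains", {
  set.seed(21)
  x <- stats::rnorm(1000)
  expect_lt(abs(psrf(list(x, x)) - 1), 0.05)
  expect_gt(psrf(list(stats::rnorm(1000), stats::rnorm(1000, 5))), 1.2)
  expect_error(psrf(list(x)), "two chains")
})

test_that("ESS recovers closed-form autocorrelation scalings", {
  set.seed(22)
  x <- stats::rnorm(10000)
  expect_lt(abs(ess(x) - 10000) / 10000, 0.15)
  ## AR(1) with coefficient 0.5: ESS/n -> (1 - phi)/(1 + phi) = 1/3
  ar <- as.vector(stats::arima.sim(list(ar = 0.5), 20000))
  expect_lt(abs(ess(ar) / 20000 - 1 / 3) / (1 / 3), 0.2)
  expect_warning(z <- ess(rep(1, 200)), "constant")
  expect_equal(z, 0)
})

test_that("identical settings and seed give bit-identical chains", {
  pat <- data.frame(n1 = 2, n2 = 2, r1 = c(0, 1), r2 = c(0, 1),
                    weight = c(40, 4))
  priors <- divergencePriors(tauMean = 0.005, alpha = concentrationPrior(1.5, 3.13))
  st <- mcmcSettings(200, 10, burnin = 1, chains = 2, seed = 42)
  t1 <- runChains(list(a = pat, b = pat), priors, st)
  t2 <- runChains(list(a = pat, b = pat), priors, st)
  expect_identical(t1$chains, t2$chains)
  expect_equal(nrow(t1$chains[[1]]), 21)
  ## zero proposal scale is rejected rather than silently freezing
  expect_error(runChains(list(a = pat), priors, st,
                         control = list(scaleTau = 0)), "positive")
})

test_that("prior-only sampling recovers every prior marginal", {
  priors <- divergencePriors(tauMean = 0.005, thetaShape = 4,
                             thetaMean = 0.004, multShape = 100, multMean = 1,
                             alpha = concentrationPrior(1.1, 56.1))
  pat <- data.frame(n1 = 1, n2 = 1, r1 = 0, r2 = 0, weight = 1)
  st <- mcmcSettings(50000, 10, burnin = 101, chains = 1, seed = 7)
  tr <- runChains(list(a = pat, b = pat, c = pat, d = pat), priors, st,
                  control = list(priorOnly = TRUE))
  post <- pooledSamples(tr)
  thin <- post[seq(1, nrow(post), by = 8), ]
  ## tau marginal: exponential
  expect_gt(stats::ks.test(jitter(thin$time_a, amount = 1e-9),
                           stats::pexp, rate = 1 / 0.005)$p.value, 0.01)
  ## theta marginal: gamma(4, mean 0.004)
  expect_gt(stats::ks.test(thin$theta1_b, stats::pgamma, shape = 4,
                           scale = 0.001)$p.value, 0.01)
  ## root multiplier marginal: gamma(100, mean 1)
  expect_gt(stats::ks.test(thin$rootmult_c, stats::pgamma, shape = 100,
                           scale = 0.01)$p.value, 0.01)
  ## alpha marginal: gamma(1.1, 56.1), mean 61.71
  expect_lt(abs(mean(post$alpha) - 1.1 * 56.1),
            4 * stats::sd(post$alpha) / sqrt(ess(post$alpha)))
  ## number of events matches the exact Dirichlet-process marginal
  pk <- probNumEventsMarginal(4, 1:4, priors$alpha)
  phat <- tabulate(thin$k, nbins = 4) / nrow(thin)
  se <- sqrt(pk * (1 - pk) / nrow(thin))
  expect_true(all(abs(phat - pk) < 4 * se + 0.01))
})

test_that("MCMC matches a brute-force grid posterior for one pair", {
  ## single comparison; theta1, theta2 fixed; tau and the root multiplier
  ## sampled. Oracle: normalised likelihood x prior on a fine grid.
  th <- 0.004
  set.seed(31)
  truthM <- pairModel(0.004, th, th, rootMultiplier = 1)
  P <- pairPatternProbs(2, 2, truthM)
  counts <- stats::rmultinom(1, 400, as.vector(P))[, 1]
  idx <- which(counts > 0)
  pat <- data.frame(n1 = 2, n2 = 2,
                    r1 = (idx - 1) %% 3, r2 = (idx - 1) %/% 3,
                    weight = counts[idx])
  priors <- divergencePriors(tauMean = 0.005, thetaShape = 4,
                             thetaMean = 0.004, multShape = 100,
                             multMean = 1, alpha = 1)
  ## grid oracle over (tau, mult)
  taus <- seq(1e-5, 0.03, length.out = 120)
  mults <- seq(0.55, 1.6, length.out = 40)
  lp <- outer(taus, mults, Vectorize(function(tt, mm)
    codivtimes:::.comparisonLogLikCpp(as.matrix(pat), tt, th, th, mm) +
      stats::dexp(tt, 1 / 0.005, log = TRUE) +
      stats::dgamma(mm, 100, scale = 0.01, log = TRUE)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  gridMeanTau <- sum(rowSums(w) * taus)
  st <- mcmcSettings(12000, 2, burnin = 501, chains = 1, seed = 11)
  tr <- runChains(list(x = pat), priors, st,
                  control = list(updateThetas = FALSE),
                  init = list(assign = 0L, times = 0.005, theta1 = th,
                              theta2 = th, rootMultiplier = 1, alpha = 1))
  post <- pooledSamples(tr)
  mcmcMeanTau <- mean(post$time_x)
  expect_lt(abs(mcmcMeanTau - gridMeanTau) / gridMeanTau, 0.1)
  ## the posterior concentrates in the right place
  expect_lt(abs(mcmcMeanTau - 0.004), 0.004)
})

test_that("weak data leave the divergence-time posterior near its prior", {
  ## 200 constant sites carry little information about tau
  pat <- data.frame(n1 = 2, n2 = 2, r1 = 0, r2 = 0, weight = 200)
  priors <- divergencePriors(tauMean = 0.005, alpha = 1)
  st <- mcmcSettings(4000, 2, burnin = 101, chains = 1, seed = 13)
  tr <- runChains(list(x = pat), priors, st)
  post <- pooledSamples(tr)
  prior <- stats::rexp(5000, 1 / 0.005)
  ## posterior mean within a factor ~1.5 of the prior mean
  expect_lt(abs(mean(post$time_x) - 0.005), 0.0035)
  expect_gt(mean(post$time_x), 0.001)
})

test_that("trace diagnostics run on real chains", {
  pat <- data.frame(n1 = 2, n2 = 2, r1 = c(0, 1), r2 = c(0, 0),
                    weight = c(90, 10))
  priors <- divergencePriors(alpha = concentrationPrior(1.5, 3.13))
  st <- mcmcSettings(2000, 2, burnin = 101, chains = 2, seed = 5)
  tr <- runChains(list(a = pat, b = pat), priors, st)
  d <- traceDiagnostics(tr)
  expect_true(all(c("ln_likelihood", "alpha", "time_a") %in% d$quantity))
  ## the Brooks-Gelman estimator can dip to sqrt((n-1)/n) below one
  expect_true(all(d$psrf[!is.na(d$psrf)] >= 0.999))
  expect_true(all(d$ess <= 2 * 900 + 2))
})
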