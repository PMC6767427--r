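test_that("two-state transition probability matches its closed form", {
  expect_equal(transitionProbSame(0), 1)
  expect_lt(abs(transitionProbSame(200) - 0.5), 1e-12)
  expect_equal(transitionProbSame(log(2) / 2), 0.75)
  expect_error(transitionProbSame(-0.1), "non-negative")
})

test_that("branch propagation matches closed forms and an expm oracle", {
  ## single lineage: 2x2 closed form
  L <- 0.037
  out <- propagateBranch(c(1, 0), 1, L, 0.004)
  ps <- transitionProbSame(L)
  expect_equal(out, c(ps, 1 - ps), tolerance = 1e-10)
  ## zero length leaves the partial unchanged
  f0 <- c(0.2, 0.8)
  expect_equal(propagateBranch(f0, 1, 0, 0.01), f0, tolerance = 1e-12)
  ## two lineages, theta -> 0+: instantaneous coalescence onto m = 1
  f <- c(0, 0, 1, 0, 0)   # unit mass at (2, 0)
  out <- propagateBranch(f, 2, 1e-4, 1e-9)
  expect_lt(abs(sum(out[1:2]) - 1), 1e-6)
  expect_lt(sum(out[3:5]), 1e-6)
  ## independent oracle: dense matrix exponential from Matrix
  skip_if_not_installed("Matrix")
  set.seed(42)
  n <- 4
  G <- codivtimes:::.generatorMatrixCpp(n, 0.01)
  f <- stats::runif(nrow(G))
  t <- 0.02
  oracle <- as.vector(Matrix::expm(Matrix::Matrix(t(G) * t)) %*% f)
  expect_equal(propagateBranch(f, n, t, 0.01), oracle, tolerance = 1e-9)
})

test_that("infinite root branch agrees with long-time propagation", {
  set.seed(7)
  for (n in c(2, 4)) {
    f <- stats::runif(n * (n + 3) / 2)
    theta <- 0.05
    inf <- propagateBranch(f, n, Inf, theta)
    long <- propagateBranch(f, n, 60 * (2 * theta + 1), theta)
    expect_lt(max(abs(inf - long)), 1e-8)
    expect_equal(sum(inf[-(1:2)]), 0)
  }
})

test_that("pattern probabilities normalise to one", {
  model <- list()
  grid <- expand.grid(tau = c(0, 0.002, 0.05), theta = c(0.001, 0.02))
  for (n1 in 0:6) for (n2 in 0:(6 - n1)) {
    if (n1 + n2 < 1) next
    for (g in seq_len(nrow(grid))) {
      m <- pairModel(grid$tau[g], grid$theta[g], 2 * grid$theta[g],
                     rootMultiplier = 1.3)
      P <- pairPatternProbs(n1, n2, m)
      expect_lt(abs(sum(P) - 1), 1e-8)
      expect_true(all(P >= 0))
    }
  }
})

test_that("two-lineage pattern probability matches the closed form", {
  ## n1 = n2 = 1, same state: 1/2 (1 + exp(-4 tau) / (1 + 8 thetaRoot))
  for (tau in c(0, 0.003, 0.02)) for (thr in c(0.002, 0.01)) {
    m <- pairModel(tau, thr, thr, rootMultiplier = 1)
    P <- pairPatternProbs(1, 1, m)
    closed <- 0.5 * (1 + exp(-4 * tau) / (1 + 8 * thr))
    expect_equal(P[1, 1] + P[2, 2], closed, tolerance = 1e-9)
  }
  ## single copy in one population: stationary 1/2 each
  m <- pairModel(0.01, 0.004, 0.004)
  expect_equal(exp(patternLogLikelihood(1, 0, 0, 0, m)), 0.5, tolerance = 1e-9)
  expect_equal(exp(patternLogLikelihood(1, 0, 1, 0, m)), 0.5, tolerance = 1e-9)
})

test_that("likelihood is symmetric under population relabelling", {
  m12 <- pairModel(0.004, 0.002, 0.008, rootMultiplier = 1.2)
  m21 <- pairModel(0.004, 0.008, 0.002, rootMultiplier = 1.2)
  pat <- data.frame(n1 = c(3, 2), n2 = c(2, 4), r1 = c(1, 0), r2 = c(2, 1),
                    weight = c(5, 3))
  swapped <- data.frame(n1 = pat$n2, n2 = pat$n1, r1 = pat$r2, r2 = pat$r1,
                        weight = pat$weight)
  expect_equal(comparisonLogLikelihood(pat, m12),
               comparisonLogLikelihood(swapped, m21), tolerance = 1e-10)
})

test_that("likelihood is invariant under global 0/1 relabelling", {
  m <- pairModel(0.006, 0.003, 0.005, rootMultiplier = 0.9)
  pat <- data.frame(n1 = c(3, 3, 2), n2 = c(3, 2, 0), r1 = c(0, 2, 1),
                    r2 = c(1, 1, 0), weight = c(10, 2, 4))
  flipped <- transform(pat, r1 = n1 - r1, r2 = n2 - r2)
  expect_equal(comparisonLogLikelihood(pat, m),
               comparisonLogLikelihood(flipped, m), tolerance = 1e-10)
})

test_that("constant-site likelihoods take their stationary values", {
  m <- pairModel(0.002, 0.004, 0.004)
  pat <- data.frame(n1 = 1, n2 = 0, r1 = 0, r2 = 0, weight = 1)
  expect_equal(comparisonLogLikelihood(pat, m), log(0.5), tolerance = 1e-9)
  expect_error(patternLogLikelihood(0, 0, 0, 0, m), "no sampled")
  expect_error(comparisonLogLikelihood(pat[0, ], m), "empty")
})

test_that("analytic likelihood agrees with the Monte-Carlo gene-tree oracle", {
  set.seed(11)
  nbad <- 0
  for (case in 1:20) {
    n1 <- sample(0:3, 1)
    n2 <- if (n1 == 0) sample(1:3, 1) else sample(0:3, 1)
    if (n1 + n2 == 0) n2 <- 1
    r1 <- if (n1) sample(0:n1, 1) else 0
    r2 <- if (n2) sample(0:n2, 1) else 0
    m <- pairModel(tau = stats::rexp(1, 1 / 0.01),
                   theta1 = stats::rgamma(1, 4, scale = 0.002),
                   theta2 = stats::rgamma(1, 4, scale = 0.002),
                   rootMultiplier = stats::rgamma(1, 100, scale = 0.01))
    o <- mcOracleLogLikelihood(n1, n2, r1, r2, m, replicates = 4000,
                               seed = 100 + case)
    analytic <- exp(patternLogLikelihood(n1, n2, r1, r2, m))
    if (abs(analytic - o["mean"]) > 3 * max(o["se"], 1e-12)) nbad <- nbad + 1
  }
  ## with 20 independent 3-sigma checks, more than 2 failures signals a bug
  expect_lte(nbad, 2)
})

test_that("exchangeability holds at tau = 0 with equal sizes", {
  th <- 0.004
  m <- pairModel(0, th, th, rootMultiplier = 1)
  ## between-population same-state probability equals within-population one
  Pb <- pairPatternProbs(1, 1, m)
  Pw <- pairPatternProbs(2, 0, m)
  expect_equal(Pb[1, 1] + Pb[2, 2], Pw[1, 1] + Pw[3, 1], tolerance = 1e-9)
  ## and matches the single-population closed form 1 - 4 theta/(1 + 8 theta)
  expect_equal(Pb[1, 1] + Pb[2, 2], 1 - 4 * th / (1 + 8 * th),
               tolerance = 1e-9)
})

test_that("likelihood monotonicity in tau and root size", {
  same <- function(tau, mult) {
    P <- pairPatternProbs(1, 1, pairModel(tau, 0.004, 0.004, mult))
    P[1, 1] + P[2, 2]
  }
  taus <- c(0, 0.001, 0.01, 0.05, 0.2)
  vals <- vapply(taus, same, 0, mult = 1)
  expect_true(all(diff(vals) <= 1e-12))
  mults <- c(0.1, 0.5, 1, 5, 20)
  vals <- vapply(mults, function(mm) same(0.001, mm), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("domain errors are raised", {
  m <- pairModel(0.01, 0.004, 0.004)
  expect_error(pairPatternProbs(2, 2, pairModel(0.01, -1, 0.004)))
  expect_error(propagateBranch(c(1, 0), 1, 0.1, -0.5), "positive")
  expect_error(propagateBranch(c(1, 0), 1, -0.1, 0.5), "non-negative")
})
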