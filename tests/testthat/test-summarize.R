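test_that("Bayes-factor arithmetic holds exactly", {
  bf <- bayesFactor(0.385, 0.5)
  expect_equal(unname(bf["for"]), 0.385 / 0.615, tolerance = 1e-12)
  expect_equal(unname(bf["against"]), 1 / unname(bf["for"]))
  expect_equal(unname(bf["for"] * bf["against"]), 1)
  expect_equal(unname(bayesFactor(0.3, 0.3)["for"]), 1)
  expect_error(bayesFactor(1, 0.5), "pseudo-sample")
  expect_error(bayesFactor(0.5, 0), "pseudo-sample")
  ## identity on a synthetic P(k) table
  pk <- c(0.1, 0.6, 0.3); prior <- c(0.2, 0.5, 0.3)
  for (k in 1:3) {
    bf <- bayesFactor(pk[k], prior[k])
    expect_equal(unname(bf["for"]),
                 (pk[k] / (1 - pk[k])) / (prior[k] / (1 - prior[k])))
  }
})

test_that("most-similar-pair prior is one minus P(all independent)", {
  p <- mostSimilarPairPrior(8, concentrationPrior(1.1, 56.1))
  expect_equal(p, 0.5, tolerance = 0.05)
  expect_equal(mostSimilarPairPrior(8, 1e9), 0, tolerance = 1e-6)
  expect_equal(mostSimilarPairPrior(8, 1e-9), 1, tolerance = 1e-6)
})

test_that("trace summaries compute P(k), Bayes factors and codivergence", {
  mkTrace <- function(k, ev1, ev2, t1, t2, chain = 1) {
    data.frame(generation = seq_along(k), ln_likelihood = 0, alpha = 1,
               k = k, event_a = ev1, time_a = t1, theta1_a = 1e-3,
               theta2_a = 1e-3, rootmult_a = 1, event_b = ev2, time_b = t2,
               theta1_b = 1e-3, theta2_b = 1e-3, rootmult_b = 1,
               chain = chain)
  }
  traces <- structure(list(
    chains = list(mkTrace(c(1, 1, 2, 2, 1), c(1, 1, 1, 1, 1),
                          c(1, 1, 2, 2, 1), rep(0.01, 5),
                          c(0.01, 0.01, 0.03, 0.02, 0.01))),
    labels = c("a", "b"),
    settings = mcmcSettings(4, 1, burnin = 0),
    priors = divergencePriors(alpha = 1)),
    class = "codivTraces")
  sm <- summarizeTraces(traces, priorK = c(0.5, 0.5))
  expect_equal(sm$pk, c(0.6, 0.4))
  expect_equal(sm$coassignment["a", "b"], 0.6)
  expect_equal(diag(sm$coassignment), c(a = 1, b = 1))
  expect_true(isSymmetric(sm$coassignment))
  expect_equal(sm$bayesFactors[1], (0.6 / 0.4) / (0.5 / 0.5))
  expect_equal(sm$tauSummary$postMean[1], 0.01)
  ## degenerate P(k) = 1 is corrected by one pseudo-sample and flagged
  tr2 <- traces
  tr2$chains[[1]]$k <- rep(1, 5)
  tr2$chains[[1]]$event_b <- rep(1, 5)
  sm2 <- summarizeTraces(tr2, priorK = c(0.5, 0.5))
  expect_true(sm2$bfBounded[1])
  expect_equal(sm2$bayesFactors[1], (5 / 6) / (1 / 6) / 1)
  ## pooled P(k) equals the weighted per-chain average
  tr3 <- traces
  tr3$chains <- list(traces$chains[[1]], mkTrace(rep(2, 5), rep(1, 5),
                                                 rep(2, 5), rep(0.01, 5),
                                                 rep(0.02, 5), chain = 2))
  sm3 <- summarizeTraces(tr3, priorK = c(0.5, 0.5))
  expect_equal(sm3$pk[2], (0.4 * 5 + 1 * 5) / 10)
})

test_that("loci split into halves that differ by at most one", {
  cd <- makeComparison(replicate(5, rbind(c(2, 2, 1, 0)), simplify = FALSE))
  halves <- vetSplit(cd, seed = 3)
  expect_equal(sort(vapply(halves, function(h) unname(h@counts["loci"]), 0)),
               c(2, 3))
  expect_equal(halves[[1]]@populations, cd@populations)
  ## deterministic under a fixed seed
  halves2 <- vetSplit(cd, seed = 3)
  expect_equal(lapply(halves, patternTable), lapply(halves2, patternTable))
  ## even split at the empirical scale: 21,426 loci -> 10,713 + 10,713
  big <- makeComparison(replicate(21426, rbind(c(1, 1, 0, 0)),
                                  simplify = FALSE))
  bigHalves <- vetSplit(big, seed = 1)
  expect_equal(vapply(bigHalves, function(h) unname(h@counts["loci"]), 0),
               c(10713, 10713))
  expect_error(vetSplit(makeComparison(list(rbind(c(1, 1, 0, 0))))),
               "at least two")
})

test_that("nucleotide diversity matches hand calculations", {
  ## identical sequences -> 0
  cd <- makeComparison(list(rbind(c(2, 2, 0, 0), c(2, 2, 0, 0))))
  expect_equal(unname(nucleotideDiversity(cd)["pi1"]), 0)
  ## two copies differing at 1 of 10 sites -> 0.1
  loci <- list(cbind(n1 = rep(2, 10), n2 = rep(0, 10),
                     r1 = c(1, rep(0, 9)), r2 = 0))
  cd <- makeComparison(loci)
  expect_equal(unname(nucleotideDiversity(cd)["pi1"]), 0.1)
  expect_true(is.na(nucleotideDiversity(cd)["pi2"]))
  ## between-population difference at every site
  cd <- makeComparison(list(rbind(c(1, 1, 0, 1))))
  expect_equal(unname(nucleotideDiversity(cd)["piBetween"]), 1)
})

test_that("performance reports aggregate truth versus estimates", {
  tauTable <- data.frame(replicate = c(1, 1, 2),
                         trueTau = c(0.01, 0.02, 0.03),
                         postMean = c(0.012, 0.02, 0.027),
                         ciLower = c(0.005, 0.021, 0.02),
                         ciUpper = c(0.02, 0.03, 0.04))
  kTable <- data.frame(replicate = 1:2, trueK = c(2, 1), estK = c(2, 2))
  rep <- performanceReport(tauTable, kTable, psrfValues = c(1.0, 1.5))
  expect_equal(rep$rmse,
               sqrt(mean(c(0.002, 0, -0.003)^2)))
  expect_equal(rep$coverage, 2 / 3)
  expect_equal(unname(rep$confusion[2, 2]), 1)
  expect_equal(unname(rep$confusion[1, 2]), 1)
  expect_equal(rep$nFlagged, 1)
  ## estimates identical to truth give zero error and full coverage
  perfect <- performanceReport(
    transform(tauTable, postMean = trueTau, ciLower = trueTau - 1e-9,
              ciUpper = trueTau + 1e-9),
    data.frame(trueK = 1, estK = 1))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$coverage, 1)
  ## posterior mode with ties broken toward smaller k
  expect_equal(posteriorModeK(c(1, 1, 2, 2, 3)), 1)
  expect_equal(posteriorModeK(c(3, 3, 2)), 3)
})

test_that("divergence-gap arithmetic reproduces the printed threshold", {
  gap <- expectedDivergenceGap(1.18e-9, 3000)
  expect_equal(gap, 3.54e-6, tolerance = 1e-3)
  expect_equal(expectedDivergenceGap(0, 3000), 0)
  ## the posterior mean gap between the two most similar pairs exceeds
  ## the within-interglacial resolution threshold by > 2.7x
  expect_gte(9.66e-6 / 3.5e-6, 2.7)
})

test_that("summary writers emit TSV and JSON", {
  mk <- data.frame(generation = 1:5, ln_likelihood = 0, alpha = 1,
                   k = c(1, 2, 1, 1, 2), event_a = 1, time_a = 0.01,
                   theta1_a = 1e-3, theta2_a = 1e-3, rootmult_a = 1,
                   event_b = c(1, 2, 1, 1, 2), time_b = 0.01,
                   theta1_b = 1e-3, theta2_b = 1e-3, rootmult_b = 1,
                   chain = 1)
  traces <- structure(list(chains = list(mk), labels = c("a", "b"),
                           settings = mcmcSettings(4, 1, burnin = 0),
                           priors = divergencePriors(alpha = 1)),
                      class = "codivTraces")
  sm <- summarizeTraces(traces, priorK = c(0.5, 0.5))
  dir <- tempfile("sumout")
  writeModelChoiceSummary(sm, dir)
  back <- read.delim(file.path(dir, "num_events.tsv"))
  expect_equal(back$posterior, c(0.6, 0.4))
  js <- jsonlite::read_json(file.path(dir, "model_choice.json"),
                            simplifyVector = TRUE)
  expect_equal(js$pk, c(0.6, 0.4))
  pr <- performanceReport(
    data.frame(trueTau = 0.01, postMean = 0.011, ciLower = 0.005,
               ciUpper = 0.02),
    data.frame(trueK = 1, estK = 1), psrfValues = 1.01)
  writePerformanceReport(pr, dir)
  back <- read.delim(file.path(dir, "performance.tsv"))
  expect_equal(back$coverage, 1)
  expect_equal(back$nFlagged, 0)
})
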