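# codivtimes

Full-likelihood Bayesian tests of *shared divergence times* among pairs of
populations, for comparative phylogeographers who want to know whether
several population splits happened together (e.g. island pairs fragmented
by the same sea-level rise) or independently.

Each of *n* population pairs is a two-tipped species tree: descendant
sizes θ₁, θ₂, ancestral size θ_root, and a divergence time τ (expected
substitutions per site; the mutation rate is fixed at 1) with no
migration afterwards.  The likelihood of biallelic (or binary-recoded)
characters is computed exactly by integrating over gene trees and
mutational histories on the lineage-count state space, under the
symmetric two-state substitution model.  A Dirichlet-process prior with
concentration α groups the pairs into divergence events:

- P(partition | α) = α^k ∏ᵢ(sᵢ − 1)! / ∏ᵢ₌₀^{n−1}(α + i), with k events
  of sizes sᵢ;
- P(k | n, α) = |s(n, k)| α^k / α^{(n)} (unsigned Stirling numbers);
- support is summarised by Bayes factors: posterior odds / prior odds.

MCMC samples the joint posterior of the partition, event times,
demographic parameters and α (Gibbs partition updates with auxiliary
components; Escobar–West update for α).  A template-matched coalescent
simulator reproduces an empirical dataset's exact sampling skeleton
(loci × sites × per-site gene copies, i.e. the same missing-data
patterns) for calibration studies.

## Worked example

Simulate two comparisons that truly codiverged, then ask the model how
many divergence events the data support:

```r
library(codivtimes)

priors <- divergencePriors(tauMean = 0.005,
                           alpha = concentrationPrior(1.5, 3.13))
tpl <- uniformTemplate(c("pairA", "pairB"), loci = 400, sites = 100,
                       copies1 = 4, copies2 = 4)
truth <- simulateReplicate(tpl, priors, seed = 1)
truth$truth$assign          # both pairs in event 1 -> a shared divergence
#> [1] 1 1

tr <- runChains(truth$data, priors,
                mcmcSettings(1200, 4, burnin = 51, chains = 2, seed = 1),
                control = list(scaleTau = 0.15, scaleTheta = 0.15,
                               scaleMult = 0.08))
sm <- summarizeTraces(tr)
round(sm$pk, 3)             # posterior P(k = 1), P(k = 2)
#> [1] 0.886 0.114
round(sm$priorK, 3)         # prior P(k) under Gamma(1.5, 3.13)
#> [1] 0.265 0.735
round(sm$bayesFactors[1], 1)  # BF for one shared event vs not
#> [1] 21.5
sm$coassignment["pairA", "pairB"]  # posterior P(both pairs in one event)
#> [1] 0.886
round(1e3 * sm$tauSummary$postMean, 3)  # tau posterior means (x 10^-3)
#> [1] 10.055 10.085
round(1e3 * truth$truth$times[1], 3)    # true shared tau (x 10^-3)
#> [1] 9.999
```

A posterior probability of 0.89 for a single shared event against a
prior of 0.27 gives a Bayes factor of ~21: strong support for
codivergence, and the shared divergence time is recovered to within a
fraction of a percent.  With real data, `readComparison()` loads
per-locus FASTA or NEXUS alignments with a population map,
`summarizeDataset()` reproduces the usual loci/sites/variable/polyallelic
counts, and `vetSplit()` implements the split-loci vetting check.  The
`commandSuite()` entry point (wrapped by `inst/scripts/codivtimes`)
drives simulate / analyze / summarize / vet runs from one YAML config.

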