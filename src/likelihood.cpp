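// Core likelihood machinery for the two-population divergence model.
//
// A site's history is tracked on the triangular state space (m, j):
// m = number of surviving ancestral lineages of the sampled gene copies
// (1..n), j = number of those lineages carrying character state 1 (0..m).
// The joint coalescent-mutation generator acts on count-space partials
// ("T-partials"): tip initialisation is a unit mass at (n, r); the merge of
// the two descendant populations at the divergence node is a plain
// convolution of their partials; and the resulting probability, after
// absorbing the infinite ancestral branch, is the probability of the
// *labelled* site pattern.  Multiplying by the binomial coefficients
// C(n1,r1) C(n2,r2) yields the probability of the observed allele-count
// pattern, and these normalise to one over all (r1, r2).
//
// Rate conventions (single place where the scaling is pinned):
//   * a specific pair of gene copies coalesces at rate 1/(2*theta),
//     theta = Ne*mu on the expected-substitutions-per-site timescale;
//   * each lineage flips character state at rate 1, the symmetric
//     two-state analogue of Jukes-Cantor with stationary frequencies
//     (1/2, 1/2), so P(same state | t) = (1 + exp(-2 t)) / 2.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int sidx(int m, int j) { return m * (m + 1) / 2 - 1 + j; }
static inline int nstates(int n) { return n * (n + 3) / 2; }
static inline double choose2(int k) { return k < 2 ? 0.0 : 0.5 * k * (k - 1); }

// pair coalescent rate for a population-size parameter theta
static inline double coalRate(double theta) { return 1.0 / (2.0 * theta); }

arma::mat generatorMatrix(int n, double theta) {
  const int ns = nstates(n);
  const double lam = coalRate(theta);
  arma::mat G(ns, ns, arma::fill::zeros);
  for (int m = 1; m <= n; ++m) {
    for (int j = 0; j <= m; ++j) {
      const int i = sidx(m, j);
      // mutation: one lineage flips state
      if (j < m) G(i, sidx(m, j + 1)) += (m - j);
      if (j > 0) G(i, sidx(m, j - 1)) += j;
      // coalescence: only like-state pairs re-enter the state space
      if (m > 1) {
        if (j >= 2)     G(i, sidx(m - 1, j - 1)) += choose2(j) * lam;
        if (m - j >= 2) G(i, sidx(m - 1, j))     += choose2(m - j) * lam;
      }
      // exit: all pairs (like or unlike) plus all mutations
      G(i, i) = -(choose2(m) * lam + m);
    }
  }
  return G;
}

// Absorption vector u for an infinite ancestral branch: for a T-partial F
// entering the root, the labelled pattern probability is (1/2) * dot(u, F).
// Entries for m = 1 are 1 (already coalesced; the surviving lineage's state
// is weighted by the (1/2, 1/2) stationary distribution via the global 1/2);
// entries for m >= 2 solve (-G_big) v = w, where w holds the direct
// absorption rates into m = 1 (like-state pairs at m = 2).
arma::vec rootAbsorptionVector(int n, double thetaRoot) {
  const int ns = nstates(n);
  arma::vec u(ns, arma::fill::ones);
  if (n < 2) return u;
  arma::mat G = generatorMatrix(n, thetaRoot);
  const int nb = ns - 2;                 // states with m >= 2 are contiguous
  arma::mat Gbig = G.submat(2, 2, ns - 1, ns - 1);
  arma::vec w(nb, arma::fill::zeros);
  const double lam = coalRate(thetaRoot);
  for (int j = 0; j <= 2; ++j)
    w(sidx(2, j) - 2) = (choose2(j) + choose2(2 - j)) * lam;
  arma::vec v = arma::solve(-Gbig, w);
  u.subvec(2, ns - 1) = v;
  return u;
}

// matrix of count-pattern probabilities P[r1, r2] for one pair model;
// n2 = 0 (or n1 = 0) handles sites with copies sampled in one population only
arma::mat pairPatternMatrix(int n1, int n2, double tau,
                            double th1, double th2, double thetaRoot) {
  if (n1 + n2 < 1) stop("site pattern with no sampled gene copies");
  if (tau < 0) stop("divergence time must be non-negative");
  if (th1 <= 0 || th2 <= 0 || thetaRoot <= 0) stop("theta must be positive");
  if (n1 == 0 || n2 == 0) {
    const int n = n1 + n2;
    const double th = (n1 == 0) ? th2 : th1;
    arma::mat M = arma::expmat(generatorMatrix(n, th).t() * tau);
    arma::vec u = rootAbsorptionVector(n, thetaRoot);
    arma::mat P(n1 + 1, n2 + 1, arma::fill::zeros);
    for (int r = 0; r <= n; ++r) {
      double p = 0.5 * arma::dot(u, M.col(sidx(n, r))) * R::choose(n, r);
      if (n1 == 0) P(0, r) = p; else P(r, 0) = p;
    }
    return P;
  }
  arma::mat M1 = arma::expmat(generatorMatrix(n1, th1).t() * tau);
  arma::mat M2 = arma::expmat(generatorMatrix(n2, th2).t() * tau);
  const int s1 = nstates(n1), s2 = nstates(n2);
  arma::vec u = rootAbsorptionVector(n1 + n2, thetaRoot);
  // K encodes the convolution merge followed by root absorption
  arma::mat K(s1, s2);
  for (int m1 = 1; m1 <= n1; ++m1)
    for (int j1 = 0; j1 <= m1; ++j1)
      for (int m2 = 1; m2 <= n2; ++m2)
        for (int j2 = 0; j2 <= m2; ++j2)
          K(sidx(m1, j1), sidx(m2, j2)) = u(sidx(m1 + m2, j1 + j2));
  arma::mat M1tip(s1, n1 + 1), M2tip(s2, n2 + 1);
  for (int r = 0; r <= n1; ++r) M1tip.col(r) = M1.col(sidx(n1, r));
  for (int r = 0; r <= n2; ++r) M2tip.col(r) = M2.col(sidx(n2, r));
  arma::mat P = 0.5 * (M1tip.t() * K * M2tip);
  for (int r1 = 0; r1 <= n1; ++r1)
    for (int r2 = 0; r2 <= n2; ++r2)
      P(r1, r2) *= R::choose(n1, r1) * R::choose(n2, r2);
  return P;
}

// [[Rcpp::export(name = ".pairPatternProbsCpp")]]
arma::mat pairPatternProbsCpp(int n1, int n2, double tau,
                              double th1, double th2, double thetaRoot) {
  return pairPatternMatrix(n1, n2, tau, th1, th2, thetaRoot);
}

// [[Rcpp::export(name = ".generatorMatrixCpp")]]
arma::mat generatorMatrixCpp(int n, double theta) {
  return generatorMatrix(n, theta);
}

// [[Rcpp::export(name = ".propagateBranchCpp")]]
arma::vec propagateBranchCpp(arma::vec partial, int n, double len, double theta) {
  if (theta <= 0) stop("theta must be positive");
  if (len < 0) stop("branch length must be non-negative");
  if ((int)partial.n_elem != nstates(n)) stop("partial has wrong length");
  if (!std::isfinite(len)) {
    arma::vec u = rootAbsorptionVector(n, theta);
    double tot = arma::dot(u, partial);
    arma::vec out(nstates(n), arma::fill::zeros);
    out(sidx(1, 0)) = 0.5 * tot;
    out(sidx(1, 1)) = 0.5 * tot;
    return out;
  }
  arma::mat M = arma::expmat(generatorMatrix(n, theta).t() * len);
  return M * partial;
}

// weighted log-likelihood of a compressed pattern table
// rows of `pat`: n1, n2, r1, r2, weight
double comparisonLogLikImpl(const arma::mat &pat, double tau,
                            double th1, double th2, double thetaRoot) {
  std::map<std::pair<int, int>, std::vector<int> > groups;
  for (arma::uword i = 0; i < pat.n_rows; ++i)
    groups[std::make_pair((int)pat(i, 0), (int)pat(i, 1))].push_back(i);
  double ll = 0.0;
  for (std::map<std::pair<int, int>, std::vector<int> >::const_iterator
         it = groups.begin(); it != groups.end(); ++it) {
    arma::mat P = pairPatternMatrix(it->first.first, it->first.second,
                                    tau, th1, th2, thetaRoot);
    for (size_t k = 0; k < it->second.size(); ++k) {
      const int i = it->second[k];
      double p = P((int)pat(i, 2), (int)pat(i, 3));
      if (p < 1e-300) p = 1e-300;   // underflow guard
      ll += pat(i, 4) * std::log(p);
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".comparisonLogLikCpp")]]
double comparisonLogLikCpp(arma::mat pat, double tau, double th1, double th2,
                           double rootMultiplier) {
  return comparisonLogLikImpl(pat, tau, th1, th2,
                              rootMultiplier * (th1 + th2) / 2.0);
}
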