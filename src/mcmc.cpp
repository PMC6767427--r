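// One MCMC chain over the joint posterior of the divergence-event
// partition, event times, per-comparison demographic parameters and the
// Dirichlet-process concentration parameter.
//
// Moves, all leaving the joint posterior invariant:
//   * event times tau_e and per-comparison theta1, theta2, root multiplier:
//     multiplicative (log-scale) random-walk Metropolis-Hastings;
//   * the partition: per-comparison Gibbs reassignment with one auxiliary
//     component (Neal 2000, algorithm 8 with m = 1); a comparison that is
//     currently alone in its event re-uses its own time as the auxiliary,
//     otherwise the auxiliary time is a fresh draw from the tau prior;
//   * alpha: the Escobar-West beta-augmentation conditional update.
//
// All randomness flows through R's RNG so set.seed() in R makes a chain
// bit-reproducible.

#include "codivtimes.h"
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Prior {
  double tauMean;
  double thetaShape, thetaScale;
  double multShape, multScale;
  double alphaShape, alphaScale;   // (shape, scale) gamma hyperprior
  bool alphaFixed;
};

double gammaLogKernel(double x, double shape, double scale) {
  return (shape - 1.0) * std::log(x) - x / scale;
}

} // namespace

// [[Rcpp::export(name = ".runChainCpp")]]
List runChainCpp(List patternTables, List priorList, List initList,
                 int generations, int interval, List control) {
  const int ncomp = patternTables.size();
  std::vector<arma::mat> pats(ncomp);
  for (int c = 0; c < ncomp; ++c) pats[c] = as<arma::mat>(patternTables[c]);

  Prior pr;
  pr.tauMean    = as<double>(priorList["tauMean"]);
  pr.thetaShape = as<double>(priorList["thetaShape"]);
  pr.thetaScale = as<double>(priorList["thetaMean"]) / pr.thetaShape;
  pr.multShape  = as<double>(priorList["multShape"]);
  pr.multScale  = as<double>(priorList["multMean"]) / pr.multShape;
  pr.alphaFixed = as<bool>(priorList["alphaFixed"]);
  pr.alphaShape = as<double>(priorList["alphaShape"]);
  pr.alphaScale = as<double>(priorList["alphaScale"]);

  std::vector<int> assign = as<std::vector<int> >(initList["assign"]);
  std::vector<double> times = as<std::vector<double> >(initList["times"]);
  std::vector<double> th1 = as<std::vector<double> >(initList["theta1"]);
  std::vector<double> th2 = as<std::vector<double> >(initList["theta2"]);
  std::vector<double> mult = as<std::vector<double> >(initList["rootMultiplier"]);
  double alpha = as<double>(initList["alpha"]);

  const bool priorOnly      = as<bool>(control["priorOnly"]);
  const bool updTau         = as<bool>(control["updateTau"]);
  const bool updTheta       = as<bool>(control["updateThetas"]);
  const bool updMult        = as<bool>(control["updateMult"]);
  const bool updPartition   = as<bool>(control["updatePartition"]);
  const bool updAlpha       = as<bool>(control["updateAlpha"]) && !pr.alphaFixed;
  const double sTau   = as<double>(control["scaleTau"]);
  const double sTheta = as<double>(control["scaleTheta"]);
  const double sMult  = as<double>(control["scaleMult"]);
  if ((updTau && sTau <= 0) || (updTheta && sTheta <= 0) || (updMult && sMult <= 0))
    stop("proposal scale must be positive");
  if (generations % interval != 0) stop("generations must be divisible by interval");

  // comparison log-likelihood given an event time, current thetas
  auto compLik = [&](int c, double tau) -> double {
    if (priorOnly) return 0.0;
    return comparisonLogLikImpl(pats[c], tau, th1[c], th2[c],
                                mult[c] * (th1[c] + th2[c]) / 2.0);
  };

  std::vector<double> compLL(ncomp);
  for (int c = 0; c < ncomp; ++c) compLL[c] = compLik(c, times[assign[c]]);

  const int nsamp = generations / interval + 1;
  const int ncol = 4 + 5 * ncomp;
  arma::mat out(nsamp, ncol);
  int accTau = 0, propTau = 0, accCont = 0, propCont = 0;

  auto record = [&](int row, int gen) {
    out(row, 0) = gen;
    double lnl = 0.0;
    for (int c = 0; c < ncomp; ++c) lnl += compLL[c];
    out(row, 1) = lnl;
    out(row, 2) = alpha;
    out(row, 3) = (double)times.size();
    for (int c = 0; c < ncomp; ++c) {
      out(row, 4 + 5 * c) = assign[c] + 1;          // 1-based in reports
      out(row, 5 + 5 * c) = times[assign[c]];
      out(row, 6 + 5 * c) = th1[c];
      out(row, 7 + 5 * c) = th2[c];
      out(row, 8 + 5 * c) = mult[c];
    }
  };
  record(0, 0);

  // renumber events by first appearance so partitions compare canonically
  auto canonicalize = [&]() {
    std::vector<int> map(times.size(), -1);
    std::vector<double> newTimes;
    int next = 0;
    for (int c = 0; c < ncomp; ++c) {
      if (map[assign[c]] < 0) {
        map[assign[c]] = next++;
        newTimes.push_back(times[assign[c]]);
      }
      assign[c] = map[assign[c]];
    }
    times = newTimes;
  };

  int row = 1;
  for (int g = 1; g <= generations; ++g) {
    // --- event times -----------------------------------------------------
    if (updTau) {
      for (size_t e = 0; e < times.size(); ++e) {
        ++propTau;
        const double tauOld = times[e];
        const double tauNew = tauOld * std::exp(R::runif(-sTau, sTau));
        double logr = -(tauNew - tauOld) / pr.tauMean + std::log(tauNew / tauOld);
        std::vector<std::pair<int, double> > newLL;
        for (int c = 0; c < ncomp; ++c) {
          if (assign[c] != (int)e) continue;
          double ll = compLik(c, tauNew);
          logr += ll - compLL[c];
          newLL.push_back(std::make_pair(c, ll));
        }
        if (std::log(R::runif(0, 1)) < logr) {
          ++accTau;
          times[e] = tauNew;
          for (size_t i = 0; i < newLL.size(); ++i)
            compLL[newLL[i].first] = newLL[i].second;
        }
      }
    }
    // --- demographic parameters -----------------------------------------
    for (int c = 0; c < ncomp; ++c) {
      const double tauC = times[assign[c]];
      for (int which = 0; which < 3; ++which) {
        if (which <= 1 && !updTheta) continue;
        if (which == 2 && !updMult) continue;
        ++propCont;
        double *par = (which == 0) ? &th1[c] : (which == 1) ? &th2[c] : &mult[c];
        const double shape = (which == 2) ? pr.multShape : pr.thetaShape;
        const double scale = (which == 2) ? pr.multScale : pr.thetaScale;
        const double s     = (which == 2) ? sMult : sTheta;
        const double oldV = *par;
        const double newV = oldV * std::exp(R::runif(-s, s));
        *par = newV;
        const double llNew = compLik(c, tauC);
        double logr = llNew - compLL[c]
          + gammaLogKernel(newV, shape, scale) - gammaLogKernel(oldV, shape, scale)
          + std::log(newV / oldV);
        if (std::log(R::runif(0, 1)) < logr) {
          ++accCont;
          compLL[c] = llNew;
        } else {
          *par = oldV;
        }
      }
    }
    // --- partition -------------------------------------------------------
    if (updPartition && ncomp > 1) {
      for (int c = 0; c < ncomp; ++c) {
        std::vector<int> size(times.size(), 0);
        for (int d = 0; d < ncomp; ++d) ++size[assign[d]];
        const int eCur = assign[c];
        --size[eCur];
        double auxTime;
        bool auxIsOwn = (size[eCur] == 0);
        if (auxIsOwn) {
          auxTime = times[eCur];
        } else {
          auxTime = R::rexp(pr.tauMean);
        }
        const int ne = times.size();
        std::vector<double> logw;
        std::vector<int> target;
        std::vector<double> cand;    // candidate log-likelihoods
        for (int e = 0; e < ne; ++e) {
          if (auxIsOwn && e == eCur) continue;
          // the current event's likelihood is already cached
          double ll = (e == eCur) ? compLL[c] : compLik(c, times[e]);
          logw.push_back(std::log((double)size[e]) + ll);
          target.push_back(e);
          cand.push_back(ll);
        }
        {
          double ll = auxIsOwn ? compLL[c] : compLik(c, auxTime);
          logw.push_back(std::log(alpha) + ll);
          target.push_back(-1);
          cand.push_back(ll);
        }
        double mx = logw[0];
        for (size_t i = 1; i < logw.size(); ++i) mx = std::max(mx, logw[i]);
        double tot = 0.0;
        for (size_t i = 0; i < logw.size(); ++i) tot += std::exp(logw[i] - mx);
        double uu = R::runif(0, 1) * tot, acc = 0.0;
        size_t pick = logw.size() - 1;
        for (size_t i = 0; i < logw.size(); ++i) {
          acc += std::exp(logw[i] - mx);
          if (uu <= acc) { pick = i; break; }
        }
        if (target[pick] == -1) {
          if (auxIsOwn) {
            // stays (or returns to) its own singleton event
            times[eCur] = auxTime;
            assign[c] = eCur;
          } else {
            times.push_back(auxTime);
            assign[c] = times.size() - 1;
          }
        } else {
          assign[c] = target[pick];
          if (auxIsOwn) {
            // drop the vacated singleton event
            times.erase(times.begin() + eCur);
            for (int d = 0; d < ncomp; ++d)
              if (assign[d] > eCur) --assign[d];
          }
        }
        compLL[c] = cand[pick];
      }
      canonicalize();
    }
    // --- concentration parameter ----------------------------------------
    if (updAlpha) {
      const int k = times.size();
      const double eta = R::rbeta(alpha + 1.0, (double)ncomp);
      const double rate = 1.0 / pr.alphaScale - std::log(eta);
      const double odds = (pr.alphaShape + k - 1.0) / (ncomp * rate);
      if (R::runif(0, 1) < odds / (1.0 + odds))
        alpha = R::rgamma(pr.alphaShape + k, 1.0 / rate);
      else
        alpha = R::rgamma(pr.alphaShape + k - 1.0, 1.0 / rate);
    }
    if (g % interval == 0) record(row++, g);
  }

  return List::create(
    _["samples"] = out,
    _["acceptance"] = List::create(
      _["tau"] = propTau ? (double)accTau / propTau : NA_REAL,
      _["continuous"] = propCont ? (double)accCont / propCont : NA_REAL));
}
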