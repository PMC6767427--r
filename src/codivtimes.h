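#ifndef CODIVTIMES_H
#define CODIVTIMES_H

#include <RcppArmadillo.h>

arma::mat generatorMatrix(int n, double theta);
arma::vec rootAbsorptionVector(int n, double thetaRoot);
arma::mat pairPatternMatrix(int n1, int n2, double tau,
                            double th1, double th2, double thetaRoot);
double comparisonLogLikImpl(const arma::mat &pat, double tau,
                            double th1, double th2, double thetaRoot);

#endif
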