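#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Site (pattern) likelihoods of the symmetric binary Mk chain by
// Felsenstein pruning, mixed over rate classes.  `edge` must be in
// postorder; `pat` is the ntip x npat 0/1 pattern matrix with rows in the
// tip-number order of the tree.
// [[Rcpp::export(".mkSiteLikC")]]
NumericVector mkSiteLikC(IntegerMatrix edge, NumericVector el, int ntip,
                         IntegerMatrix pat, NumericVector rates,
                         NumericVector weights) {
  const int nE = edge.nrow();
  const int npat = pat.ncol();
  int nn = ntip;
  for (int e = 0; e < nE; ++e) {
    if (edge(e, 0) > nn) nn = edge(e, 0);
    if (edge(e, 1) > nn) nn = edge(e, 1);
  }
  NumericVector out(npat);
  std::vector<double> L0((size_t)nn * npat), L1((size_t)nn * npat);
  std::vector<char> touched(nn);
  const int root = edge(nE - 1, 0) - 1;
  for (int k = 0; k < rates.size(); ++k) {
    const double r = rates[k], w = weights[k];
    std::fill(touched.begin(), touched.end(), 0);
    for (int e = 0; e < nE; ++e) {
      const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      const double ee = std::exp(-2.0 * r * el[e]);
      const double ps = (1.0 + ee) / 2.0, pd = (1.0 - ee) / 2.0;
      double *P0 = &L0[(size_t)p * npat], *P1 = &L1[(size_t)p * npat];
      if (c < ntip) {
        if (touched[p]) {
          for (int j = 0; j < npat; ++j) {
            const double c1 = (double)pat(c, j), c0 = 1.0 - c1;
            P0[j] *= ps * c0 + pd * c1;
            P1[j] *= pd * c0 + ps * c1;
          }
        } else {
          for (int j = 0; j < npat; ++j) {
            const double c1 = (double)pat(c, j), c0 = 1.0 - c1;
            P0[j] = ps * c0 + pd * c1;
            P1[j] = pd * c0 + ps * c1;
          }
          touched[p] = 1;
        }
      } else {
        const double *C0 = &L0[(size_t)c * npat], *C1 = &L1[(size_t)c * npat];
        if (touched[p]) {
          for (int j = 0; j < npat; ++j) {
            P0[j] *= ps * C0[j] + pd * C1[j];
            P1[j] *= pd * C0[j] + ps * C1[j];
          }
        } else {
          for (int j = 0; j < npat; ++j) {
            P0[j] = ps * C0[j] + pd * C1[j];
            P1[j] = pd * C0[j] + ps * C1[j];
          }
          touched[p] = 1;
        }
      }
    }
    const double *R0 = &L0[(size_t)root * npat], *R1 = &L1[(size_t)root * npat];
    for (int j = 0; j < npat; ++j) out[j] += w * 0.5 * (R0[j] + R1[j]);
  }
  return out;
}
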