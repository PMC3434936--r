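#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Log-likelihood and its gradient with respect to every branch length, for
// the symmetric binary Mk chain mixed over rate classes.  `edge` must be in
// postorder, `pat` is the ntip x npat 0/1 pattern matrix (tip-number row
// order), `wpat` the pattern weights.  Root marginalisation uses the uniform
// prior (1/2, 1/2).
// [[Rcpp::export(".mkLikGradC")]]
List mkLikGradC(IntegerMatrix edge, NumericVector el, int ntip,
                IntegerMatrix pat, NumericVector wpat,
                NumericVector rates, NumericVector wrate) {
  const int nE = edge.nrow();
  const int npat = pat.ncol();
  const int K = rates.size();
  int nn = ntip;
  for (int e = 0; e < nE; ++e) {
    if (edge(e, 0) > nn) nn = edge(e, 0);
    if (edge(e, 1) > nn) nn = edge(e, 1);
  }
  const int root = edge(nE - 1, 0) - 1;

  // per-class storage: down partials D, above partials U, per-edge messages M
  std::vector<double> D0((size_t)nn * npat), D1((size_t)nn * npat);
  std::vector<double> U0((size_t)nn * npat), U1((size_t)nn * npat);
  std::vector<double> M0((size_t)nE * npat), M1((size_t)nE * npat);
  std::vector<double> sl(npat);                       // mixed site lik
  std::vector<double> dsl((size_t)nE * npat);         // mixed d site lik/dt
  std::vector<char> touched(nn);
  std::vector<int> edgeOfNode(nn, -1);                // edge above each node

  for (int e = 0; e < nE; ++e) edgeOfNode[edge(e, 1) - 1] = e;

  for (int k = 0; k < K; ++k) {
    const double r = rates[k], w = wrate[k];
    std::fill(touched.begin(), touched.end(), 0);
    // down pass: D at internal nodes, M per edge
    for (int e = 0; e < nE; ++e) {
      const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      const double ee = std::exp(-2.0 * r * el[e]);
      const double ps = (1.0 + ee) / 2.0, pd = (1.0 - ee) / 2.0;
      double *m0 = &M0[(size_t)e * npat], *m1 = &M1[(size_t)e * npat];
      if (c < ntip) {
        for (int j = 0; j < npat; ++j) {
          const double c1 = (double)pat(c, j), c0 = 1.0 - c1;
          D0[(size_t)c * npat + j] = c0;
          D1[(size_t)c * npat + j] = c1;
          m0[j] = ps * c0 + pd * c1;
          m1[j] = pd * c0 + ps * c1;
        }
      } else {
        const double *C0 = &D0[(size_t)c * npat], *C1 = &D1[(size_t)c * npat];
        for (int j = 0; j < npat; ++j) {
          m0[j] = ps * C0[j] + pd * C1[j];
          m1[j] = pd * C0[j] + ps * C1[j];
        }
      }
      double *P0 = &D0[(size_t)p * npat], *P1 = &D1[(size_t)p * npat];
      if (touched[p]) {
        for (int j = 0; j < npat; ++j) { P0[j] *= m0[j]; P1[j] *= m1[j]; }
      } else {
        for (int j = 0; j < npat; ++j) { P0[j] = m0[j]; P1[j] = m1[j]; }
        touched[p] = 1;
      }
    }
    // site likelihood contribution
    {
      const double *R0 = &D0[(size_t)root * npat], *R1 = &D1[(size_t)root * npat];
      for (int j = 0; j < npat; ++j) sl[j] += w * 0.5 * (R0[j] + R1[j]);
    }
    // up pass (reverse postorder): U at child = sum_a G_a P_ab, where
    // G_a = U_parent,a * prod of sibling messages
    for (int j = 0; j < npat; ++j) {
      U0[(size_t)root * npat + j] = 0.5;
      U1[(size_t)root * npat + j] = 0.5;
    }
    for (int e = nE - 1; e >= 0; --e) {
      const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      const double ee = std::exp(-2.0 * r * el[e]);
      const double ps = (1.0 + ee) / 2.0, pd = (1.0 - ee) / 2.0;
      const double dps = -r * ee, dpd = r * ee;   // d/dt of ps, pd
      const double *m0 = &M0[(size_t)e * npat], *m1 = &M1[(size_t)e * npat];
      const double *Pp0 = &D0[(size_t)p * npat], *Pp1 = &D1[(size_t)p * npat];
      const double *Up0 = &U0[(size_t)p * npat], *Up1 = &U1[(size_t)p * npat];
      const double *C0 = &D0[(size_t)c * npat], *C1 = &D1[(size_t)c * npat];
      double *uc0 = &U0[(size_t)c * npat], *uc1 = &U1[(size_t)c * npat];
      double *g = &dsl[(size_t)e * npat];
      for (int j = 0; j < npat; ++j) {
        // sibling product = D_parent / message  (guard zero messages)
        double g0 = (m0[j] > 0) ? Up0[j] * (Pp0[j] / m0[j]) : 0.0;
        double g1 = (m1[j] > 0) ? Up1[j] * (Pp1[j] / m1[j]) : 0.0;
        uc0[j] = g0 * ps + g1 * pd;
        uc1[j] = g0 * pd + g1 * ps;
        g[j] += w * (g0 * (dps * C0[j] + dpd * C1[j]) +
                     g1 * (dpd * C0[j] + dps * C1[j]));
      }
    }
  }
  double ll = 0.0;
  for (int j = 0; j < npat; ++j) ll += wpat[j] * std::log(sl[j]);
  NumericVector grad(nE);
  for (int e = 0; e < nE; ++e) {
    double ge = 0.0;
    const double *g = &dsl[(size_t)e * npat];
    for (int j = 0; j < npat; ++j) ge += wpat[j] * g[j] / sl[j];
    grad[e] = ge;
  }
  return List::create(_["logLik"] = ll, _["gradient"] = grad);
}
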