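// Felsenstein pruning over compressed site patterns.
// Plain Rcpp: 4-state models, discrete-gamma mixture, per-node rescaling.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// edge: 2-column matrix in postorder (parent, child), 1-based ape numbering.
// tip_partials: list of 4 x npat matrices, one per tip (1..ntip).
// brlen: expected substitutions per site for each edge (category rate and
//   partition rate multipliers are applied here by the caller, except the
//   per-category multiplier which is applied inside the category loop).
// U, Uinv, eval: spectral decomposition of the normalised rate matrix.
// cat_rates: discrete-gamma category rates (equiprobable categories).
// [[Rcpp::export]]
double peel_loglik_cpp(const IntegerMatrix& edge,
                       const int ntip,
                       const int nnode,
                       const NumericVector& brlen,
                       const List& tip_partials,
                       const NumericVector& weights,
                       const NumericMatrix& U,
                       const NumericMatrix& Uinv,
                       const NumericVector& eval,
                       const NumericVector& pi,
                       const NumericVector& cat_rates) {
  const int nedge = edge.nrow();
  const int npat = weights.size();
  const int ncat = cat_rates.size();
  const int nvert = ntip + nnode;
  if (npat == 0) stop("zero-length alignment");

  std::vector<double> sitelik(npat, 0.0);
  std::vector<double> sitescale(npat, 0.0);  // shared log scalers (cat 0 sets)
  std::vector<double> part(4 * npat);
  std::vector<double> acc((size_t)4 * npat * nvert);
  std::vector<char> seen(nvert);
  double P[16];

  // cache tip partial pointers
  std::vector<NumericMatrix> tp;
  tp.reserve(ntip);
  for (int i = 0; i < ntip; ++i) tp.push_back(as<NumericMatrix>(tip_partials[i]));

  for (int c = 0; c < ncat; ++c) {
    std::fill(acc.begin(), acc.end(), 1.0);
    std::fill(seen.begin(), seen.end(), 0);
    std::vector<double> scale(npat, 0.0);

    for (int e = 0; e < nedge; ++e) {
      const int u = edge(e, 0) - 1;
      const int v = edge(e, 1) - 1;
      const double t = brlen[e] * cat_rates[c];
      // P = U diag(exp(eval*t)) Uinv
      double ex[4];
      for (int k = 0; k < 4; ++k) ex[k] = std::exp(eval[k] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += U(i, k) * ex[k] * Uinv(k, j);
          P[4 * i + j] = s > 0.0 ? s : 0.0;
        }
      // child partials
      const double* cp;
      if (v < ntip) {
        cp = REAL(tp[v]);
      } else {
        cp = &acc[(size_t)4 * npat * v];
      }
      double* up = &acc[(size_t)4 * npat * u];
      for (int s = 0; s < npat; ++s) {
        double w[4];
        const double* col = cp + 4 * s;
        for (int i = 0; i < 4; ++i)
          w[i] = P[4 * i] * col[0] + P[4 * i + 1] * col[1] +
                 P[4 * i + 2] * col[2] + P[4 * i + 3] * col[3];
        double* ucol = up + 4 * s;
        for (int i = 0; i < 4; ++i) ucol[i] *= w[i];
      }
      seen[u] = 1;
      // rescale the parent column after its last child was folded in
      bool last = true;
      for (int e2 = e + 1; e2 < nedge; ++e2)
        if (edge(e2, 0) - 1 == u) { last = false; break; }
      if (last) {
        for (int s = 0; s < npat; ++s) {
          double* ucol = up + 4 * s;
          double mx = ucol[0];
          for (int i = 1; i < 4; ++i) if (ucol[i] > mx) mx = ucol[i];
          if (mx > 0.0 && mx < 1e-100) {
            for (int i = 0; i < 4; ++i) ucol[i] /= mx;
            scale[s] += std::log(mx);
          }
        }
      }
    }
    const int root = ntip;  // ape root = ntip + 1 (1-based)
    const double* rp = &acc[(size_t)4 * npat * root];
    for (int s = 0; s < npat; ++s) {
      double lik = 0.0;
      for (int i = 0; i < 4; ++i) lik += pi[i] * rp[4 * s + i];
      if (c == 0) {
        sitescale[s] = scale[s];
        sitelik[s] = lik;
      } else {
        // bring to the shared scaling before accumulating the category mix
        sitelik[s] += lik * std::exp(scale[s] - sitescale[s]);
      }
    }
  }
  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    if (!(sitelik[s] > 0.0)) {
      stop("non-finite likelihood at site pattern %d", s + 1);
    }
    ll += weights[s] * (std::log(sitelik[s] / ncat) + sitescale[s]);
  }
  return ll;
}
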