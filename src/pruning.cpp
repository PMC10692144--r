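#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning log-likelihood for a fixed rooted topology under a
// reversible amino-acid model given by its eigendecomposition
// (Q = U diag(lam) Uinv, stationary frequencies pi), with discrete
// rate categories of equal weight.  Edges must be in postorder (children
// before parents); `blen` is expected substitutions per site per edge.
// `patterns` holds residue codes 0..19 per tip (row) and site pattern
// (column); negative codes mean fully ambiguous (gap/X).  Per-node
// rescaling keeps partials in range on deep trees.
// [[Rcpp::export]]
double prune_loglik_cpp(IntegerMatrix edge, int ntip, int nnode,
                        NumericVector blen, IntegerMatrix patterns,
                        NumericVector weights, NumericMatrix U,
                        NumericMatrix Uinv, NumericVector lam,
                        NumericVector pi, NumericVector cat_rates) {
  const int S = 20;
  const int npat = patterns.ncol();
  const int ncat = cat_rates.size();
  const int ntot = ntip + nnode;
  const int root = ntip;  // 0-based index of ape node ntip + 1
  std::vector<double> sitell(npat * ncat);
  std::vector<double> P(S * S), expl(S);

  for (int cat = 0; cat < ncat; ++cat) {
    std::vector<std::vector<double>> part(ntot);
    std::vector<std::vector<double>> lsc(ntot);
    for (int e = 0; e < edge.nrow(); ++e) {
      int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      double t = blen[e] * cat_rates[cat];
      if (t < 0) stop("negative branch length");
      // P = U diag(exp(lam * t)) Uinv
      for (int i = 0; i < S; ++i) expl[i] = std::exp(lam[i] * t);
      for (int i = 0; i < S; ++i)
        for (int j = 0; j < S; ++j) {
          double s = 0;
          for (int k = 0; k < S; ++k) s += U(i, k) * expl[k] * Uinv(k, j);
          P[i * S + j] = s > 0 ? s : 0;
        }
      if (part[p].empty()) {
        part[p].assign(S * npat, 1.0);
        lsc[p].assign(npat, 0.0);
      }
      if (c < ntip) {
        for (int m = 0; m < npat; ++m) {
          int code = patterns(c, m);
          if (code < 0) continue;  // ambiguous tip: row sums are 1
          for (int i = 0; i < S; ++i)
            part[p][i * npat + m] *= P[i * S + code];
        }
      } else {
        // rescale the child partial before consuming it
        for (int m = 0; m < npat; ++m) {
          double mx = 0;
          for (int i = 0; i < S; ++i) {
            double v = part[c][i * npat + m];
            if (v > mx) mx = v;
          }
          if (mx <= 0) stop("zero partial likelihood: data impossible");
          for (int i = 0; i < S; ++i) part[c][i * npat + m] /= mx;
          lsc[p][m] += lsc[c][m] + std::log(mx);
        }
        for (int m = 0; m < npat; ++m) {
          for (int i = 0; i < S; ++i) {
            double s = 0;
            for (int j = 0; j < S; ++j)
              s += P[i * S + j] * part[c][j * npat + m];
            part[p][i * npat + m] *= s;
          }
        }
      }
    }
    for (int m = 0; m < npat; ++m) {
      double v = 0;
      for (int i = 0; i < S; ++i) v += pi[i] * part[root][i * npat + m];
      sitell[m * ncat + cat] = std::log(v) + lsc[root][m];
    }
  }
  // combine categories (equal weights) with log-sum-exp, then sum patterns
  double total = 0;
  for (int m = 0; m < npat; ++m) {
    double mx = sitell[m * ncat];
    for (int cat = 1; cat < ncat; ++cat)
      if (sitell[m * ncat + cat] > mx) mx = sitell[m * ncat + cat];
    double s = 0;
    for (int cat = 0; cat < ncat; ++cat)
      s += std::exp(sitell[m * ncat + cat] - mx);
    total += weights[m] * (mx + std::log(s / ncat));
  }
  return total;
}
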