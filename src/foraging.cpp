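#include <Rcpp.h>
using namespace Rcpp;

// Iterated foraging fixed point within one patch.
//
// S     : C x P feeding scores of the local consumers (rows) on the local
//         species (cols); entries <= 0 mean "not prey".
// alpha : C x C competition coefficients between the consumers.
// Nc    : consumer populations (length C).
// Np    : populations of all local species (length P).
// sat   : functional-response saturation constant.
//
// Starting from efforts uniform over each consumer's prey set, alternately
// applies the ratio-dependent functional response
//   g[i][j] = S[i][j] f[i][j] Np[j] / (sat Np[j] + sum_k alpha[i][k] S[k][j] f[k][j] Nc[k])
// and the effort normalization f[i][j] = g[i][j] / sum_j g[i][j],
// synchronously over all consumers, until the maximum absolute change in f
// falls below tol or maxit iterations are reached.
// [[Rcpp::export]]
List forage_fixed_point(NumericMatrix S, NumericMatrix alpha,
                        NumericVector Nc, NumericVector Np,
                        double sat, int maxit, double tol) {
  const int C = S.nrow(), P = S.ncol();
  NumericMatrix f(C, P), g(C, P);

  // uniform initial efforts over each consumer's prey set
  for (int i = 0; i < C; ++i) {
    int k = 0;
    for (int j = 0; j < P; ++j) if (S(i, j) > 0.0) ++k;
    if (k > 0) {
      double u = 1.0 / k;
      for (int j = 0; j < P; ++j) f(i, j) = (S(i, j) > 0.0) ? u : 0.0;
    }
  }

  std::vector<double> W(C);  // S[k][j] f[k][j] Nc[k] for current prey j
  int it = 0;
  double delta = R_PosInf;
  for (it = 0; it < maxit; ++it) {
    // g from f (synchronous)
    for (int j = 0; j < P; ++j) {
      for (int k = 0; k < C; ++k)
        W[k] = (S(k, j) > 0.0) ? S(k, j) * f(k, j) * Nc[k] : 0.0;
      for (int i = 0; i < C; ++i) {
        if (S(i, j) > 0.0) {
          double den = sat * Np[j];
          for (int k = 0; k < C; ++k)
            if (W[k] != 0.0) den += alpha(i, k) * W[k];
          g(i, j) = (den > 0.0) ? S(i, j) * f(i, j) * Np[j] / den : 0.0;
        } else {
          g(i, j) = 0.0;
        }
      }
    }
    // f from g, track the largest effort change
    delta = 0.0;
    for (int i = 0; i < C; ++i) {
      double rs = 0.0;
      for (int j = 0; j < P; ++j) rs += g(i, j);
      if (rs > 0.0) {
        for (int j = 0; j < P; ++j) {
          double fn = g(i, j) / rs;
          double d = std::abs(fn - f(i, j));
          if (d > delta) delta = d;
          f(i, j) = fn;
        }
      }
    }
    if (delta < tol) { ++it; break; }
  }

  // leave g consistent with the returned efforts
  for (int j = 0; j < P; ++j) {
    for (int k = 0; k < C; ++k)
      W[k] = (S(k, j) > 0.0) ? S(k, j) * f(k, j) * Nc[k] : 0.0;
    for (int i = 0; i < C; ++i) {
      if (S(i, j) > 0.0) {
        double den = sat * Np[j];
        for (int k = 0; k < C; ++k)
          if (W[k] != 0.0) den += alpha(i, k) * W[k];
        g(i, j) = (den > 0.0) ? S(i, j) * f(i, j) * Np[j] / den : 0.0;
      }
    }
  }

  return List::create(_["f"] = f, _["g"] = g,
                      _["iterations"] = it, _["delta"] = delta);
}
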