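// Inner loop of the composite-likelihood sweep scan: for every grid point,
// maximize the sweep-model log composite likelihood over the
// alpha/lambda/rho grids against the background SFS log-likelihood.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List clr_grid_cpp(NumericVector pos, NumericVector p0s, NumericVector is1,
                  NumericVector grid, double L, NumericVector alphas,
                  NumericVector lambdas, NumericVector rhos, double pi0) {
  int G = grid.size(), S = pos.size();
  int nA = alphas.size(), nL = lambdas.size(), nR = rhos.size();
  NumericVector clr(G), alpha_hat(G);
  std::vector<double> k(S);
  double ll0 = 0.0;
  for (int s = 0; s < S; ++s) ll0 += std::log(p0s[s]);
  for (int g = 0; g < G; ++g) {
    double gp = grid[g];
    double best = ll0, best_a = alphas[nA - 1];
    for (int ia = 0; ia < nA; ++ia) {
      double a = alphas[ia];
      for (int s = 0; s < S; ++s) {
        double d = std::fabs(pos[s] - gp);
        if (d < 1.0) d = 1.0;
        k[s] = std::exp(-a * d);
      }
      double I = (2.0 - std::exp(-a * gp) - std::exp(-a * (L - gp))) / a;
      for (int il = 0; il < nL; ++il) {
        double lam = lambdas[il];
        for (int ir = 0; ir < nR; ++ir) {
          double rho = rhos[ir];
          double ll = 0.0;
          for (int s = 0; s < S; ++s) {
            double w = lam * k[s];
            ll += std::log((1.0 - w) * p0s[s] + w * rho * is1[s]);
          }
          ll += (1.0 - rho) * pi0 * lam * I;
          if (ll > best) { best = ll; best_a = a; }
        }
      }
    }
    clr[g] = 2.0 * (best - ll0);
    alpha_hat[g] = best_a;
  }
  return List::create(_["clr"] = clr, _["alpha_hat"] = alpha_hat);
}
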