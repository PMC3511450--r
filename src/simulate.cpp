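#include <Rcpp.h>
using namespace Rcpp;

// Normalized Hill transfer function: f(x) = a * H(x) / H(1),
// H(x) = x^n / (p^n + x^n).  f(0) = 0, f(1) = a, strictly increasing on (0,1).
static inline double hill_tf(double x, double a, double p, double n) {
  if (x <= 0.0) return 0.0;
  double pn = std::pow(p, n);
  double xn = std::pow(x, n);
  return a * (xn / (pn + xn)) * (pn + 1.0);
}

// Pseudo-steady-state simulation of a gated logic network.
//
// react:  2 x n_r integer matrix of reactant indices (1-based, 0 = unused)
// inhib:  length-n_r inhibitor index (1-based, 0 = none)
// prod:   length-n_r product index (1-based)
// clamp:  n_s x n_e matrix; NA = free species, otherwise the clamped value
//
// Each experiment starts from x = 0 on free species and iterates the
// synchronous update x_j <- OR_{i in T_j} z_i, z_i = f(prod(R_i) * prod(1-I_i))
// until the maximum absolute change drops below tol.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(IntegerMatrix react, IntegerVector inhib, IntegerVector prod,
                  NumericVector a, NumericVector p, double n,
                  NumericMatrix clamp, double tol, int maxit) {
  const int n_r = prod.size();
  const int n_s = clamp.nrow();
  const int n_e = clamp.ncol();

  NumericMatrix x(n_s, n_e), z(n_r, n_e);
  LogicalVector converged(n_e);
  IntegerVector iters(n_e);
  std::vector<double> xk(n_s), xnew(n_s), zk(n_r);

  for (int k = 0; k < n_e; ++k) {
    for (int j = 0; j < n_s; ++j) {
      double c = clamp(j, k);
      xk[j] = NumericMatrix::is_na(c) ? 0.0 : c;
    }
    int it = 0;
    double delta = R_PosInf;
    while (it < maxit && delta > tol) {
      // reaction activities from the current state
      for (int i = 0; i < n_r; ++i) {
        double u = 1.0;
        for (int s = 0; s < 2; ++s) {
          int rj = react(s, i);
          if (rj > 0) u *= xk[rj - 1];
        }
        if (inhib[i] > 0) u *= (1.0 - xk[inhib[i] - 1]);
        zk[i] = hill_tf(u, a[i], p[i], n);
      }
      // synchronous OR-combination into products (probabilistic sum)
      for (int j = 0; j < n_s; ++j) xnew[j] = 0.0;
      for (int i = 0; i < n_r; ++i) {
        int j = prod[i] - 1;
        xnew[j] = xnew[j] + zk[i] - xnew[j] * zk[i];
      }
      delta = 0.0;
      for (int j = 0; j < n_s; ++j) {
        if (!NumericMatrix::is_na(clamp(j, k))) { xnew[j] = xk[j]; continue; }
        double d = std::fabs(xnew[j] - xk[j]);
        if (d > delta) delta = d;
        xk[j] = xnew[j];
      }
      ++it;
    }
    converged[k] = (delta <= tol);
    iters[k] = it;
    for (int j = 0; j < n_s; ++j) x(j, k) = xk[j];
    for (int i = 0; i < n_r; ++i) {
      double u = 1.0;
      for (int s = 0; s < 2; ++s) {
        int rj = react(s, i);
        if (rj > 0) u *= xk[rj - 1];
      }
      if (inhib[i] > 0) u *= (1.0 - xk[inhib[i] - 1]);
      z(i, k) = hill_tf(u, a[i], p[i], n);
    }
  }
  return List::create(_["x"] = x, _["z"] = z,
                      _["converged"] = converged, _["iterations"] = iters);
}
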