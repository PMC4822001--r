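#include <Rcpp.h>
using namespace Rcpp;

// Draw a state sequence from a row-stochastic matrix using R's RNG stream.
// cumT: n x n matrix of row-wise cumulative probabilities (last column == 1).
// start: 0-based start state. Returns 0-based states of length n_steps.
// [[Rcpp::export(name = ".markov_chain_cpp")]]
IntegerVector markov_chain_cpp(NumericMatrix cumT, int start, int n_steps) {
  int n = cumT.nrow();
  IntegerVector out(n_steps);
  int s = start;
  out[0] = s;
  for (int t = 1; t < n_steps; ++t) {
    double u = unif_rand();
    int j = 0;
    while (j < n - 1 && u > cumT(s, j)) ++j;
    s = j;
    out[t] = s;
  }
  return out;
}

// Overdamped Euler-Maruyama on a quartic multi-well potential.
// betaU(x) = sum_k h[k] * (x_k^2 - 1)^2 (separable, dim = length(h)).
// dx_k = -D * dbetaU/dx_k * dt + sqrt(2 D dt) * N(0,1).
// Returns (n_steps+1) x dim matrix including the start point.
// Throws if a coordinate becomes non-finite (time step too large).
// [[Rcpp::export(name = ".brownian_quartic_cpp")]]
NumericMatrix brownian_quartic_cpp(NumericVector h, NumericVector x0,
                                   double diffusion, double dt, int n_steps) {
  int dim = h.size();
  NumericMatrix out(n_steps + 1, dim);
  std::vector<double> x(dim);
  for (int k = 0; k < dim; ++k) {
    x[k] = x0[k];
    out(0, k) = x[k];
  }
  double noise = std::sqrt(2.0 * diffusion * dt);
  for (int t = 1; t <= n_steps; ++t) {
    for (int k = 0; k < dim; ++k) {
      double grad = 4.0 * h[k] * x[k] * (x[k] * x[k] - 1.0);
      x[k] += -diffusion * grad * dt + noise * norm_rand();
      if (!std::isfinite(x[k]))
        stop("non-finite coordinate at step %d; reduce dt", t);
      out(t, k) = x[k];
    }
  }
  return out;
}
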