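#include <Rcpp.h>
using namespace Rcpp;

// Single-site sampler for a {0,1}-domain Ising model.
//
// One "iteration" flips/resamples a single node from its full conditional
//   P(x_i = 1 | x_-i) = logistic(tau_i + sum_j W_ij x_j),
// visiting nodes in a fixed sequential sweep order. When sweep = true, an
// iteration is a full sweep (n single-site updates). Uses R's RNG, so
// set.seed() on the R side gives bit-identical chains.
//
// Returns the kept states: every `thin`-th iteration after `burn_in`.
// [[Rcpp::export]]
IntegerMatrix gibbs_chain_cpp(NumericVector tau, NumericMatrix W,
                              IntegerVector init, int iterations,
                              int burn_in, int thin, bool sweep) {
  const int n = tau.size();
  std::vector<int> x(init.begin(), init.end());
  // running local field: field[i] = sum_j W(i,j) * x[j]
  std::vector<double> field(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double f = 0.0;
    for (int j = 0; j < n; ++j) f += W(i, j) * x[j];
    field[i] = f;
  }
  const int kept = (iterations > burn_in) ? (iterations - burn_in + thin - 1) / thin : 0;
  IntegerMatrix out(kept, n);
  int row = 0;
  int node = 0;
  for (int t = 1; t <= iterations; ++t) {
    const int updates = sweep ? n : 1;
    for (int u = 0; u < updates; ++u) {
      const int i = node;
      node = (node + 1) % n;
      const double p1 = 1.0 / (1.0 + std::exp(-(tau[i] + field[i])));
      const int xi_new = (unif_rand() < p1) ? 1 : 0;
      if (xi_new != x[i]) {
        const double d = xi_new - x[i];
        for (int j = 0; j < n; ++j) {
          if (j != i) field[j] += d * W(j, i);
        }
        x[i] = xi_new;
      }
    }
    if (t > burn_in && (t - burn_in - 1) % thin == 0) {
      for (int j = 0; j < n; ++j) out(row, j) = x[j];
      ++row;
    }
  }
  return out;
}
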