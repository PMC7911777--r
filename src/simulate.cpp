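#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time stochastic LIF trial, explicit voltage/threshold mechanics.
//
// Step rule (reset-before-integrate, V reset to 0):
//   omega_k(n) = 1  iff  V_k(n) >= theta
//   V_k(n+1)   = gamma * V_k(n) * (1 - omega_k(n))
//                + sum_j W(k,j) omega_j(n) + I0 + S_k(n) + sigmaB * xi_k(n)
// with V_k(n_min) = 0.  Columns of S / omega index times n_min .. n_min+L-1.
// Uses R's RNG (rnorm), so set.seed() upstream gives bit-identical rasters.
// [[Rcpp::export]]
List sim_lif_threshold(int N, int L, double gamma, double theta, double I0,
                       double sigmaB, NumericMatrix W, NumericMatrix S,
                       bool keep_voltage) {
  IntegerMatrix omega(N, L);
  NumericMatrix Vout = keep_voltage ? NumericMatrix(N, L) : NumericMatrix(0, 0);
  std::vector<double> V(N, 0.0), Vnew(N);
  for (int n = 0; n < L; ++n) {
    for (int k = 0; k < N; ++k) {
      if (!R_finite(V[k]))
        stop("non-finite voltage at neuron %d, step %d", k + 1, n + 1);
      omega(k, n) = (V[k] >= theta) ? 1 : 0;
      if (keep_voltage) Vout(k, n) = V[k];
    }
    for (int k = 0; k < N; ++k) {
      double syn = 0.0;
      for (int j = 0; j < N; ++j)
        if (omega(j, n)) syn += W(k, j);
      Vnew[k] = gamma * V[k] * (1 - omega(k, n)) + syn + I0 + S(k, n) +
                sigmaB * R::rnorm(0.0, 1.0);
    }
    V = Vnew;
  }
  if (keep_voltage) return List::create(_["omega"] = omega, _["V"] = Vout);
  return List::create(_["omega"] = omega);
}

// Memory-truncated variant: spikes are drawn as Bernoulli(Pi(X)) where X is
// computed from inputs integrated over at most `memory` steps since the last
// reset (no spike within the window => integrate from the window start).
// Samples exactly the depth-`memory` Markov truncation of the model.
// [[Rcpp::export]]
IntegerMatrix sim_lif_truncated(int N, int L, double gamma, double theta,
                                double I0, double sigmaB, NumericMatrix W,
                                NumericMatrix S, int memory) {
  IntegerMatrix omega(N, L);
  // input(k, l) = synaptic + I0 + S drive entering between steps l and l+1
  NumericMatrix input(N, L);
  double g2 = gamma * gamma;
  for (int n = 0; n < L; ++n) {
    for (int k = 0; k < N; ++k) {
      int lo = n - memory;
      if (lo < 0) lo = 0;
      double v = 0.0, s2 = 0.0;
      for (int l = lo; l < n; ++l) {
        double keep = omega(k, l) ? 0.0 : 1.0;
        v = gamma * v * keep + input(k, l);
        s2 = g2 * s2 * keep + sigmaB * sigmaB;
      }
      double p;
      if (n == 0) {
        // history start: V = 0 deterministically, mirror threshold rule
        p = (0.0 >= theta) ? 1.0 : 0.0;
        omega(k, n) = (p >= 1.0) ? 1 : 0;
        continue;
      }
      p = R::pnorm((theta - v) / std::sqrt(s2), 0.0, 1.0, 0, 0); // upper tail
      omega(k, n) = (R::runif(0.0, 1.0) < p) ? 1 : 0;
    }
    for (int k = 0; k < N; ++k) {
      double syn = 0.0;
      for (int j = 0; j < N; ++j)
        if (omega(j, n)) syn += W(k, j);
      input(k, n) = syn + I0 + S(k, n);
    }
  }
  return omega;
}
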