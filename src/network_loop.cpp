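#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x)) through the removable singularity at 0
static inline double vtrap(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 / (1.0 - 0.5 * x);
  return x / (-std::expm1(-x));
}

static inline double clamp01(double z) {
  if (z < 0.0) return 0.0;
  if (z > 1.0) return 1.0;
  return z;
}

// Per-step forward-Euler integration of the whole network.
//
// Each step: (1) the clamped driver node's voltage is overwritten from the
// white-noise series; (2) every free neuron's synaptic current is
// i_scale * sum_i W(i, j) * 0.5 * (1 + tanh((V_i - theta) / sigma)) over its
// in-edges; (3) gating variables advance by one Euler step of
// dz/dt = alpha (1 - z) - beta z (h rates divided by stickiness s, gates
// clamped to [0, 1]), then the membrane voltage by one Euler step of
// C dV/dt = -m^3 h gNa (V - VNa) - n^4 gK (V - VK) - gl (V - Vl) + I.
//
// W rows are presynaptic, columns postsynaptic. Noise is generated in R so
// that all randomness is governed by R seeds. Returns n_nodes x n_steps
// voltages recorded after each step.
// [[Rcpp::export(.run_network_cpp)]]
NumericMatrix run_network_cpp(NumericMatrix W, int clamped,
                              NumericVector noise,
                              NumericVector V0, NumericVector m0,
                              NumericVector n0, NumericVector h0,
                              double C, double gNa, double gK, double gl,
                              double VNa, double VK, double Vl,
                              double s, double theta, double sigma,
                              double i_scale, double dt) {
  const int n = W.nrow();
  const int n_steps = noise.size();
  if (W.ncol() != n) stop("weight matrix must be square");
  if (clamped < 0 || clamped >= n) stop("invalid clamped node index");

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> nn(n0.begin(), n0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> f(n), I(n);
  NumericMatrix out(n, n_steps);

  for (int t = 0; t < n_steps; ++t) {
    V[clamped] = noise[t];
    for (int i = 0; i < n; ++i)
      f[i] = 0.5 * (1.0 + std::tanh((V[i] - theta) / sigma));
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += W(i, j) * f[i];
      I[j] = i_scale * acc;
    }
    for (int j = 0; j < n; ++j) {
      if (j == clamped) { out(j, t) = V[j]; continue; }
      const double v = V[j];
      const double am = vtrap(0.1 * (v + 40.0));
      const double bm = 4.0 * std::exp(-0.05 * (v + 65.0));
      const double an = 0.1 * vtrap(0.1 * (v + 55.0));
      const double bn = 0.25 * std::exp(-0.0125 * (v + 65.0));
      const double ah = 0.07 * std::exp(-0.05 * (v + 65.0)) / s;
      const double bh = 1.0 / (std::exp(-0.1 * (v + 35.0)) + 1.0) / s;
      m[j]  = clamp01(m[j]  + dt * (am * (1.0 - m[j])  - bm * m[j]));
      nn[j] = clamp01(nn[j] + dt * (an * (1.0 - nn[j]) - bn * nn[j]));
      h[j]  = clamp01(h[j]  + dt * (ah * (1.0 - h[j])  - bh * h[j]));
      const double m3h = m[j] * m[j] * m[j] * h[j];
      const double n4 = nn[j] * nn[j] * nn[j] * nn[j];
      const double dV = -m3h * gNa * (v - VNa) - n4 * gK * (v - VK)
                        - gl * (v - Vl) + I[j];
      V[j] = v + dt / C * dV;
      if (!std::isfinite(V[j]))
        stop("numerical blow-up at neuron %d, step %d", j, t + 1);
      out(j, t) = V[j];
    }
  }
  return out;
}
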