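#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the coupled vegetation / red-noise system:
//   v[k+1] = v[k] + (dt/tau_v) * (tanh(a + b*P[k] + c*F[k] + d*v[k] + N[k]) - v[k])
//   N[k+1] = N[k] - N[k]*dt/tau_N + sqrt(dt)*sigma*W[k]/tau_N
// The noise draws W are supplied by the caller so that the R and C++ engines
// consume an identical stream (reproducibility contract).
//
// `n_spin` spin-up steps are integrated first, holding the forcing at its
// first value; they consume the first `n_spin` entries of W and are not
// stored.  The returned vectors have the same length as P.

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericVector P, NumericVector F,
                  double a, double b, double c, double d,
                  double tau_v, double tau_N, double sigma,
                  double dt, double v0, double N0,
                  NumericVector W, int n_spin) {
  const R_xlen_t n = P.size();
  if (F.size() != n) stop("P and F must have equal length");
  if (W.size() < n_spin + n - 1) stop("noise vector too short");

  NumericVector v(n), N(n);
  double vk = v0, Nk = N0;
  const double rv = dt / tau_v;
  const double rN = dt / tau_N;
  const double sN = std::sqrt(dt) * sigma / tau_N;

  R_xlen_t w = 0;
  for (int k = 0; k < n_spin; ++k) {
    const double R = a + b * P[0] + c * F[0] + d * vk + Nk;
    const double v_next = vk + rv * (std::tanh(R) - vk);
    Nk = Nk - Nk * rN + sN * W[w++];
    vk = v_next;
  }
  v[0] = vk;
  N[0] = Nk;
  for (R_xlen_t k = 0; k + 1 < n; ++k) {
    const double R = a + b * P[k] + c * F[k] + d * vk + Nk;
    const double v_next = vk + rv * (std::tanh(R) - vk);
    Nk = Nk - Nk * rN + sN * W[w++];
    vk = v_next;
    v[k + 1] = vk;
    N[k + 1] = Nk;
  }
  return List::create(_["v"] = v, _["N"] = N);
}
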