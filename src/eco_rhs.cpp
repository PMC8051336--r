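#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compiled right-hand side of the three-variable evolution system, used by
// the integrator for speed. Mirrors the R reference implementation
// (compute_rates(), series_coefficients(), truncate_sums(), eco_rhs())
// term for term; the test suite asserts agreement between the two paths.
//
// par layout: k_in, k_aSx, k_Sx, k_d, K_D, K_E, p_C, p_D
// returns: x_t, C_t, D_t, n_used, converged, W, Y, H

// [[Rcpp::export]]
NumericVector eco_rhs_core(double x, double C, double D, NumericVector par,
                           int n_max, double rtol_series) {
  const double kin = par[0], ka = par[1], ks = par[2], kd = par[3],
               KD = par[4], KE = par[5], pC = par[6], pD = par[7];

  // crowding function, overflow-safe in both exponent directions
  double H;
  const double z = x / KE - 1.0;
  if (x == 0.0) {
    H = 0.0;
  } else if (z >= 0.0) {
    H = kd * x / (KD * std::exp(-std::min(z, 700.0)) + x);
  } else {
    const double ez = std::exp(z);
    H = kd * x * ez / (KD + x * ez);
  }
  const double W = (ka + ks * x) * (1.0 - x / C);
  const double Y = kd + D * H;

  const int N = n_max;
  std::vector<double> u(N + 1), w(N + 1);
  u[0] = ks * (kin + x * (ka + ks * x));
  u[1] = -(kin * (ka + 2.0 * ks * x) + x * (ka + ks * x) * (ka + 3.0 * ks * x));
  u[2] = x * x * (ka + 2.0 * ks * x) * (ka + ks * x);
  const double A = pC * x * (ka + ks * x) * (ka + ks * x);
  u[3] = -A * u[1];
  w[0] = -ks * x;
  w[1] = (ka + 2.0 * ks * x) * x;
  w[2] = 0.0;
  w[3] = -A * w[1];
  for (int i = 4; i <= N; ++i) {
    u[i] = A * ((i - 3) * x * u[i - 3] - (i - 2) * u[i - 2]);
    w[i] = A * ((i - 3) * x * w[i - 3] - (i - 2) * w[i - 2]);
  }

  // term sequences of the two series and their partial sums
  std::vector<double> tC(N + 1, 0.0), tD(N + 1), m(N + 1, 0.0),
      SCp(N + 1, 0.0), SDp(N + 1, 0.0);
  const double invC = 1.0 / C;
  double cp = 1.0;
  tD[0] = w[0];
  SDp[0] = tD[0];
  double maxm = 0.0;
  for (int i = 1; i <= N; ++i) {
    cp *= invC;
    tC[i] = i * (u[i] + Y * w[i]) * cp;
    tD[i] = w[i] * cp;
    m[i] = std::max(std::fabs(tC[i]), std::fabs(tD[i]));
    SCp[i] = SCp[i - 1] + tC[i];
    SDp[i] = SDp[i - 1] + tD[i];
    if (m[i] > maxm) maxm = m[i];
  }

  // adaptive stopping rule with optimal (smallest-term) fallback
  int n_used = N;
  bool converged = false;
  if (maxm == 0.0) {
    n_used = std::min(3, N);
    converged = true;
  } else {
    const double tiny = 1e-300;
    for (int i = 4; i <= N; ++i) {
      const double rel =
          m[i] / std::max(std::max(std::fabs(SCp[i]), std::fabs(SDp[i])), tiny);
      const double relp =
          m[i - 1] /
          std::max(std::max(std::fabs(SCp[i - 1]), std::fabs(SDp[i - 1])), tiny);
      if (rel < rtol_series && relp < rtol_series) {
        n_used = i;
        converged = true;
        break;
      }
      if (i >= 6 && m[i] > m[i - 1] && m[i - 1] > m[i - 2]) {
        int jmin = 1;
        for (int j = 2; j <= i - 2; ++j)
          if (m[j] < m[jmin]) jmin = j;
        n_used = jmin;
        converged = false;
        break;
      }
    }
  }

  const double SC = SCp[n_used], SD = SDp[n_used];
  NumericVector out(8);
  out[0] = kin + x * (W - Y);
  out[1] = -pC * W * SC;
  out[2] = pD * W * D * H * SD;
  out[3] = n_used;
  out[4] = converged ? 1.0 : 0.0;
  out[5] = W;
  out[6] = Y;
  out[7] = H;
  return out;
}
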