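#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gamma-index search: for each reference point, minimise
//   sqrt(|r - e|^2 / DTA^2 + (D_e - D_r)^2 / (f * Dnorm)^2)
// over the (resampled) evaluated distribution stored on a regular grid.
// The search walks expanding Chebyshev shells around the nearest grid node
// and stops once the purely spatial term of the next shell already exceeds
// the best gamma found, which is exact (matches exhaustive search).
//
// refc: n x d reference coordinates (mm); refd: reference doses.
// evalv: evaluated values on a regular grid with edims/eorg/estep (d <= 3).
// local: denominator uses the reference point's own dose, else global_norm.
// radius: Euclidean search cap in mm (Inf = uncapped).
// [[Rcpp::export]]
NumericVector cpp_gamma_search(NumericMatrix refc, NumericVector refd,
                               NumericVector evalv, IntegerVector edims,
                               NumericVector eorg, NumericVector estep,
                               double ddfrac, double dta, double radius,
                               bool local, double global_norm) {
  int d = edims.size();
  int n = refc.nrow();
  const double *ev = REAL(evalv);
  int nx = edims[0], ny = d > 1 ? edims[1] : 1, nz = d > 2 ? edims[2] : 1;
  double minstep = estep[0];
  for (int a = 1; a < d; ++a) minstep = std::min(minstep, estep[a]);
  double rad2 = R_FINITE(radius) ? radius * radius : R_PosInf;
  int kmax = 0;
  for (int a = 0; a < d; ++a) kmax = std::max(kmax, edims[a]);
  if (R_FINITE(radius))
    kmax = std::min(kmax, (int)std::ceil(radius / minstep) + 2);
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double rx = refc(p, 0);
    double ry = d > 1 ? refc(p, 1) : 0.0;
    double rz = d > 2 ? refc(p, 2) : 0.0;
    double Dr = refd[p];
    double denom = ddfrac * (local ? Dr : global_norm);
    double denom2 = denom * denom;
    int i0 = (int)std::lround((rx - eorg[0]) / estep[0]);
    int j0 = d > 1 ? (int)std::lround((ry - eorg[1]) / estep[1]) : 0;
    int k0 = d > 2 ? (int)std::lround((rz - eorg[2]) / estep[2]) : 0;
    double best = R_PosInf;
    for (int s = 0; s <= kmax; ++s) {
      if (s > 0) {
        double dmin = (s - 1) * minstep;
        if (dmin * dmin / (dta * dta) >= best) break;
      }
      bool any = false;
      int klo = d > 2 ? k0 - s : 0, khi = d > 2 ? k0 + s : 0;
      int jlo = d > 1 ? j0 - s : 0, jhi = d > 1 ? j0 + s : 0;
      for (int k = klo; k <= khi; ++k) {
        if (d > 2 && (k < 0 || k >= nz)) continue;
        for (int j = jlo; j <= jhi; ++j) {
          if (d > 1 && (j < 0 || j >= ny)) continue;
          bool faceJK = (d > 2 && std::abs(k - k0) == s) ||
                        (d > 1 && std::abs(j - j0) == s);
          int istep = (faceJK || s == 0) ? 1 : 2 * s;
          for (int i = i0 - s; i <= i0 + s; i += istep) {
            if (i < 0 || i >= nx) continue;
            any = true;
            double ex = eorg[0] + i * estep[0];
            double dx = ex - rx;
            double dist2 = dx * dx;
            if (d > 1) {
              double dy = eorg[1] + j * estep[1] - ry;
              dist2 += dy * dy;
            }
            if (d > 2) {
              double dz = eorg[2] + k * estep[2] - rz;
              dist2 += dz * dz;
            }
            if (dist2 > rad2) continue;
            R_xlen_t lin = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            double dd = ev[lin] - Dr;
            double g2 = dist2 / (dta * dta) + dd * dd / denom2;
            if (g2 < best) best = g2;
          }
        }
      }
      if (!any && s > kmax) break;
    }
    out[p] = std::sqrt(best);
    if ((p & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
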