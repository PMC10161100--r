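#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Grid convention (shared with the R side): values stored x-fastest, origin is
// the world-mm centre of voxel [1,1,1], bounding box extends half a voxel
// beyond the outermost centres. Densities in g/cm3, lengths in mm, so a
// 1 mm step through unit density contributes 0.1 g/cm2.

struct GridSpec {
  const double *v;
  int n[3];
  double sp[3], lo[3], hi[3];
};

static GridSpec make_spec(const NumericVector &vals, const IntegerVector &dims,
                          const NumericVector &sp, const NumericVector &org) {
  GridSpec g;
  g.v = REAL(vals);
  for (int a = 0; a < 3; ++a) {
    g.n[a] = dims[a];
    g.sp[a] = sp[a];
    g.lo[a] = org[a] - 0.5 * sp[a];
    g.hi[a] = org[a] + (dims[a] - 0.5) * sp[a];
  }
  return g;
}

// Clip segment p0->p1 (parametrised t in [0,1]) to the grid box.
static bool clip_box(const GridSpec &g, const double *p0, const double *d,
                     double &t0, double &t1) {
  t0 = 0.0; t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p0[a] < g.lo[a] || p0[a] > g.hi[a]) return false;
    } else {
      double ta = (g.lo[a] - p0[a]) / d[a];
      double tb = (g.hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t0 < t1;
}

static inline int vox_index(const GridSpec &g, const double *p, int *idx) {
  for (int a = 0; a < 3; ++a) {
    int i = (int)std::floor((p[a] - g.lo[a]) / g.sp[a]);
    if (i < 0) i = 0;
    if (i >= g.n[a]) i = g.n[a] - 1;
    idx[a] = i;
  }
  return idx[0] + g.n[0] * (idx[1] + g.n[1] * idx[2]);
}

// Exact voxel-traversal line integral of density (Amanatides-Woo).
// Returns radiological depth in g/cm2; dgeom gets the in-grid path in mm.
static double rad_depth(const GridSpec &g, const double *p0, const double *p1,
                        double *dgeom = nullptr) {
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (dgeom) *dgeom = 0.0;
  if (L < 1e-12) return 0.0;
  double t0, t1;
  if (!clip_box(g, p0, d, t0, t1)) return 0.0;
  if (dgeom) *dgeom = (t1 - t0) * L;
  double pstart[3];
  double teps = 1e-9;
  for (int a = 0; a < 3; ++a) pstart[a] = p0[a] + (t0 + teps) * d[a];
  int idx[3];
  vox_index(g, pstart, idx);
  double tMax[3], tDelta[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      step[a] = 0; tMax[a] = R_PosInf; tDelta[a] = R_PosInf;
    } else if (d[a] > 0) {
      step[a] = 1;
      tMax[a] = (g.lo[a] + (idx[a] + 1) * g.sp[a] - p0[a]) / d[a];
      tDelta[a] = g.sp[a] / d[a];
    } else {
      step[a] = -1;
      tMax[a] = (g.lo[a] + idx[a] * g.sp[a] - p0[a]) / d[a];
      tDelta[a] = -g.sp[a] / d[a];
    }
  }
  double acc = 0.0, t = t0;
  while (t < t1 - 1e-12) {
    int ax = 0;
    if (tMax[1] < tMax[ax]) ax = 1;
    if (tMax[2] < tMax[ax]) ax = 2;
    double tn = tMax[ax] < t1 ? tMax[ax] : t1;
    double seg = (tn - t) * L;
    if (seg > 0) {
      int lin = idx[0] + g.n[0] * (idx[1] + g.n[1] * idx[2]);
      acc += g.v[lin] * seg;
    }
    t = tn;
    if (tMax[ax] >= t1) break;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= g.n[ax]) break;
    tMax[ax] += tDelta[ax];
  }
  return acc * 0.1;  // g/cm3 * mm -> g/cm2
}

// [[Rcpp::export]]
NumericVector cpp_rad_depth(NumericVector rho, IntegerVector dims,
                            NumericVector sp, NumericVector org,
                            NumericMatrix P0, NumericMatrix P1) {
  GridSpec g = make_spec(rho, dims, sp, org);
  int n = P0.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a[3] = {P0(i, 0), P0(i, 1), P0(i, 2)};
    double b[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    out[i] = rad_depth(g, a, b);
  }
  return out;
}

static inline double beam_profile(double r, double Rf, double sig) {
  double s = sig * M_SQRT2;
  return 0.5 * (std::erf((Rf - r) / s) + std::erf((Rf + r) / s));
}

// Primary dose from a set of focused beams onto an output grid.
// spos/aim: per-beam source position and aim point (shot centre), mm.
// par columns: OF, mu (cm2/g), Rf (mm, field radius at focus), sigma (mm,
// penumbra), weight. Penumbra width is scaled by radiological/geometric depth.
// [[Rcpp::export]]
NumericVector cpp_primary_dose(NumericVector rho, IntegerVector dims,
                               NumericVector sp, NumericVector org,
                               NumericMatrix spos, NumericMatrix aim,
                               NumericMatrix par,
                               IntegerVector odims, NumericVector osp,
                               NumericVector oorg, double rcut_extra = 10.0) {
  GridSpec g = make_spec(rho, dims, sp, org);
  int nx = odims[0], ny = odims[1], nz = odims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  int m = spos.nrow();
  for (int s = 0; s < m; ++s) {
    double S[3] = {spos(s, 0), spos(s, 1), spos(s, 2)};
    double A[3] = {aim(s, 0), aim(s, 1), aim(s, 2)};
    double ax[3] = {A[0] - S[0], A[1] - S[1], A[2] - S[2]};
    double Lsf = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    for (int a = 0; a < 3; ++a) ax[a] /= Lsf;
    double OF = par(s, 0), mu = par(s, 1), Rf = par(s, 2), sig = par(s, 3),
           w = par(s, 4);
    double rcut = Rf + rcut_extra;
    R_xlen_t lin = 0;
    for (int k = 0; k < nz; ++k) {
      double z = oorg[2] + k * osp[2];
      for (int j = 0; j < ny; ++j) {
        double y = oorg[1] + j * osp[1];
        for (int i = 0; i < nx; ++i, ++lin) {
          double x = oorg[0] + i * osp[0];
          double v[3] = {x - S[0], y - S[1], z - S[2]};
          double t = v[0] * ax[0] + v[1] * ax[1] + v[2] * ax[2];
          if (t < 1e-6) continue;
          double per2 = 0.0;
          for (int a = 0; a < 3; ++a) {
            double c = v[a] - t * ax[a];
            per2 += c * c;
          }
          double scale = Lsf / t;           // project off-axis to focal plane
          double r = std::sqrt(per2) * scale;
          if (r > rcut) continue;
          double P[3] = {x, y, z}, dg = 0.0;
          double dr = rad_depth(g, S, P, &dg);
          double ratio = dg > 1e-6 ? dr / (0.1 * dg) : 1.0;
          if (ratio < 0.3) ratio = 0.3;
          if (ratio > 3.0) ratio = 3.0;
          o[lin] += w * OF * scale * scale * std::exp(-mu * dr) *
                    beam_profile(r, Rf, sig * ratio);
        }
      }
    }
    if (s % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Stochastic kernel engine. Histories pick a (shot, sector, collimator)
// category by the sector-sampling probabilities, a source uniformly among the
// sector's block of rows, and an aim point uniformly in the focal disc.
// Energy/mass is deposited along the ray as exp(-mu * d_rad) * seglen / vol,
// with at most one scatter redirect at an exponentially sampled depth.
// cat columns: sector (0-based), aimx, aimy, aimz, Rf, weight, mu.
// Returns list(mean, se) of per-history dose.
// [[Rcpp::export]]
List cpp_mc_lite(NumericVector rho, IntegerVector dims, NumericVector sp,
                 NumericVector org, NumericMatrix spos, int per_sector,
                 NumericMatrix cat, NumericVector prob,
                 IntegerVector odims, NumericVector osp, NumericVector oorg,
                 double n_hist, int n_batch, double scat_sd = 0.35) {
  GridSpec g = make_spec(rho, dims, sp, org);
  GridSpec go;  // output grid geometry (values unused)
  for (int a = 0; a < 3; ++a) {
    go.n[a] = odims[a];
    go.sp[a] = osp[a];
    go.lo[a] = oorg[a] - 0.5 * osp[a];
    go.hi[a] = oorg[a] + (odims[a] - 0.5) * osp[a];
  }
  double ovol = osp[0] * osp[1] * osp[2];
  R_xlen_t N = (R_xlen_t)odims[0] * odims[1] * odims[2];
  std::vector<double> sum(N, 0.0), sumsq(N, 0.0), buf(N, 0.0);
  int K = cat.nrow();
  IntegerVector counts(K);
  std::vector<double> cum(K);
  double c = 0;
  for (int k = 0; k < K; ++k) { c += prob[k]; cum[k] = c; }
  RNGScope scope;
  R_xlen_t per_batch = (R_xlen_t)(n_hist / n_batch);
  for (int b = 0; b < n_batch; ++b) {
    std::fill(buf.begin(), buf.end(), 0.0);
    for (R_xlen_t h = 0; h < per_batch; ++h) {
      double u = unif_rand() * cum[K - 1];
      int k = 0;
      while (k < K - 1 && u > cum[k]) ++k;
      ++counts[k];
      int sec = (int)cat(k, 0);
      int srow = sec * per_sector + (int)(unif_rand() * per_sector);
      if (srow >= spos.nrow()) srow = spos.nrow() - 1;
      double S[3] = {spos(srow, 0), spos(srow, 1), spos(srow, 2)};
      double A[3] = {cat(k, 1), cat(k, 2), cat(k, 3)};
      double Rf = cat(k, 4), w = cat(k, 5), mu = cat(k, 6);
      double ax[3] = {A[0] - S[0], A[1] - S[1], A[2] - S[2]};
      double L = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
      for (int a = 0; a < 3; ++a) ax[a] /= L;
      // orthonormal basis of the focal plane
      double e1[3], e2[3];
      if (std::fabs(ax[0]) < 0.9) { e1[0] = 0; e1[1] = -ax[2]; e1[2] = ax[1]; }
      else { e1[0] = -ax[1]; e1[1] = ax[0]; e1[2] = 0; }
      double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
      for (int a = 0; a < 3; ++a) e1[a] /= n1;
      e2[0] = ax[1] * e1[2] - ax[2] * e1[1];
      e2[1] = ax[2] * e1[0] - ax[0] * e1[2];
      e2[2] = ax[0] * e1[1] - ax[1] * e1[0];
      double rr = Rf * std::sqrt(unif_rand());
      double th = 2 * M_PI * unif_rand();
      double Q[3];
      for (int a = 0; a < 3; ++a)
        Q[a] = A[a] + rr * (std::cos(th) * e1[a] + std::sin(th) * e2[a]);
      double dir[3] = {Q[0] - S[0], Q[1] - S[1], Q[2] - S[2]};
      double Ld = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
      for (int a = 0; a < 3; ++a) dir[a] /= Ld;
      double tau = exp_rand();  // scatter at d_rad = tau / mu (g/cm2)
      double dscat = tau / mu;
      double drad = 0.0;
      double P0[3] = {S[0], S[1], S[2]};
      double D[3] = {dir[0], dir[1], dir[2]};
      for (int leg = 0; leg < 2; ++leg) {
        // march from P0 along D to grid exit
        double far = 2000.0;
        double P1[3] = {P0[0] + far * D[0], P0[1] + far * D[1],
                        P0[2] + far * D[2]};
        double d[3] = {P1[0] - P0[0], P1[1] - P0[1], P1[2] - P0[2]};
        double t0, t1;
        if (!clip_box(g, P0, d, t0, t1)) break;
        double step_mm = 0.5 * std::min(std::min(g.sp[0], g.sp[1]), g.sp[2]);
        double tstep = step_mm / far;
        bool scattered = false;
        double t = t0 + 0.5 * tstep;
        for (; t < t1; t += tstep) {
          double P[3] = {P0[0] + t * far * D[0], P0[1] + t * far * D[1],
                         P0[2] + t * far * D[2]};
          int idx[3];
          bool inside = true;
          for (int a = 0; a < 3; ++a)
            if (P[a] < g.lo[a] || P[a] > g.hi[a]) inside = false;
          if (!inside) continue;
          int lin = vox_index(g, P, idx);
          drad += g.v[lin] * step_mm * 0.1;
          // deposit into output grid if covered
          bool oin = true;
          for (int a = 0; a < 3; ++a)
            if (P[a] < go.lo[a] || P[a] > go.hi[a]) oin = false;
          if (oin) {
            int oi[3];
            int ol = 0;
            for (int a = 0; a < 3; ++a) {
              int ii = (int)std::floor((P[a] - go.lo[a]) / go.sp[a]);
              if (ii < 0) ii = 0;
              if (ii >= go.n[a]) ii = go.n[a] - 1;
              oi[a] = ii;
            }
            ol = oi[0] + go.n[0] * (oi[1] + go.n[1] * oi[2]);
            buf[ol] += w * std::exp(-mu * drad) * step_mm / ovol;
          }
          if (leg == 0 && drad > dscat) { scattered = true; break; }
        }
        if (!scattered) break;
        // redirect by a Gaussian angular kick and continue
        for (int a = 0; a < 3; ++a)
          P0[a] = P0[a] + t * far * D[a];
        double nd[3];
        for (int a = 0; a < 3; ++a) nd[a] = D[a] + scat_sd * norm_rand();
        double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
        for (int a = 0; a < 3; ++a) D[a] = nd[a] / nn;
      }
      if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    for (R_xlen_t i = 0; i < N; ++i) {
      double bm = buf[i] / per_batch;  // per-history batch mean
      sum[i] += bm;
      sumsq[i] += bm * bm;
    }
  }
  // batch method: grand mean and sd(batch means)/sqrt(n_batch)
  NumericVector mean(N), se(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    double m = sum[i] / n_batch;
    mean[i] = m;
    double var = sumsq[i] / n_batch - m * m;
    var = var > 0 ? var * n_batch / (n_batch - 1.0) : 0.0;
    se[i] = std::sqrt(var / n_batch);
  }
  return List::create(_["mean"] = mean, _["se"] = se,
                      _["counts"] = counts);
}

// Connected-component labelling of a binary mask, 4-connectivity in 2D and
// 6-connectivity in 3D. Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  int nd = dims.size();
  int nx = dims[0], ny = nd > 1 ? dims[1] : 1, nz = nd > 2 ? dims[2] : 1;
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                             {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
      for (int o = 0; o < 6; ++o) {
        int ii = i + off[o][0], jj = j + off[o][1], kk = k + off[o][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
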