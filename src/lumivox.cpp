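// Compiled core: trilinear sampling, gradients, transfer-function lookup,
// recursive photon tracing with transmit/reflect splitting, and the
// fusion ray caster. All geometry is in physical mm, voxel-centre
// convention: voxel (i,j,k) sits at origin + (i,j,k) * spacing, 0-based.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Grid {
  const double* d;
  int nx, ny, nz;
  double sx, sy, sz;   // spacing (mm)
  double ox, oy, oz;   // physical position of voxel (0,0,0) centre
};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double voxel(const Grid& g, int i, int j, int k) {
  return g.d[(size_t)i + (size_t)g.nx * ((size_t)j + (size_t)g.ny * k)];
}

// trilinear interpolation in clamped index space; ux/uy/uz are continuous
// voxel indices. Degenerate axes (n == 1) collapse to the single slab.
static double sampleIndex(const Grid& g, double ux, double uy, double uz) {
  ux = clampd(ux, 0.0, g.nx - 1.0);
  uy = clampd(uy, 0.0, g.ny - 1.0);
  uz = clampd(uz, 0.0, g.nz - 1.0);
  int i0 = (int)std::floor(ux); if (i0 > g.nx - 2) i0 = g.nx >= 2 ? g.nx - 2 : 0;
  int j0 = (int)std::floor(uy); if (j0 > g.ny - 2) j0 = g.ny >= 2 ? g.ny - 2 : 0;
  int k0 = (int)std::floor(uz); if (k0 > g.nz - 2) k0 = g.nz >= 2 ? g.nz - 2 : 0;
  int i1 = g.nx >= 2 ? i0 + 1 : 0;
  int j1 = g.ny >= 2 ? j0 + 1 : 0;
  int k1 = g.nz >= 2 ? k0 + 1 : 0;
  double fx = clampd(ux - i0, 0.0, 1.0);
  double fy = clampd(uy - j0, 0.0, 1.0);
  double fz = clampd(uz - k0, 0.0, 1.0);
  double c00 = voxel(g, i0, j0, k0) * (1 - fx) + voxel(g, i1, j0, k0) * fx;
  double c10 = voxel(g, i0, j1, k0) * (1 - fx) + voxel(g, i1, j1, k0) * fx;
  double c01 = voxel(g, i0, j0, k1) * (1 - fx) + voxel(g, i1, j0, k1) * fx;
  double c11 = voxel(g, i0, j1, k1) * (1 - fx) + voxel(g, i1, j1, k1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double samplePhys(const Grid& g, double px, double py, double pz) {
  return sampleIndex(g, (px - g.ox) / g.sx, (py - g.oy) / g.sy, (pz - g.oz) / g.sz);
}

// central differences in index space, one-sided (with the true index gap)
// at the faces; returns intensity units per mm.
static void gradientPhys(const Grid& g, double px, double py, double pz, double out[3]) {
  double u[3] = { (px - g.ox) / g.sx, (py - g.oy) / g.sy, (pz - g.oz) / g.sz };
  int n[3] = { g.nx, g.ny, g.nz };
  double sp[3] = { g.sx, g.sy, g.sz };
  for (int a = 0; a < 3; ++a) {
    double ua = clampd(u[a], 0.0, n[a] - 1.0);
    double up = clampd(ua + 1.0, 0.0, n[a] - 1.0);
    double um = clampd(ua - 1.0, 0.0, n[a] - 1.0);
    double gap = (up - um) * sp[a];
    if (gap <= 0) { out[a] = 0.0; continue; }
    double q[3] = { u[0], u[1], u[2] };
    q[a] = up; double vp = sampleIndex(g, q[0], q[1], q[2]);
    q[a] = um; double vm = sampleIndex(g, q[0], q[1], q[2]);
    out[a] = (vp - vm) / gap;
  }
}

struct TFTable {
  const double* v;     // n control values, ascending
  const double* rgba;  // column-major n x 4
  int n;
};

static void tfEval(const TFTable& tf, double x, double out[4]) {
  int n = tf.n;
  if (x <= tf.v[0]) {
    for (int c = 0; c < 4; ++c) out[c] = tf.rgba[c * n];
    return;
  }
  if (x >= tf.v[n - 1]) {
    for (int c = 0; c < 4; ++c) out[c] = tf.rgba[c * n + n - 1];
    return;
  }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (tf.v[mid] <= x) lo = mid; else hi = mid;
  }
  double dv = tf.v[hi] - tf.v[lo];
  double t = dv > 0 ? (x - tf.v[lo]) / dv : 1.0;
  for (int c = 0; c < 4; ++c) {
    double a = tf.rgba[c * n + lo], b = tf.rgba[c * n + hi];
    out[c] = a + (b - a) * t;
  }
}

// slab intersection with the volume's full voxel-extent box
// [origin - spacing/2, origin + (n-1)*spacing + spacing/2]
static bool boxIntersect(const Grid& g, const double o[3], const double d[3],
                         double& t0, double& t1) {
  double lo[3] = { g.ox - 0.5 * g.sx, g.oy - 0.5 * g.sy, g.oz - 0.5 * g.sz };
  double hi[3] = { g.ox + (g.nx - 0.5) * g.sx, g.oy + (g.ny - 0.5) * g.sy,
                   g.oz + (g.nz - 0.5) * g.sz };
  t0 = -INFINITY; t1 = INFINITY;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-15) {
      if (o[a] < lo[a] || o[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - o[a]) / d[a];
      double tb = (hi[a] - o[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

struct TraceCfg {
  double step;        // absolute mm
  double eps;         // termination energy as a fraction of the root
                      // photon's initial energy (absolute value is set per
                      // photon by the caller)
  double F0;          // Fresnel reflectance at normal incidence
  int maxDepth;       // reflection recursion depth cap
  double gradThresh;  // min |gradient| for a defined reflection normal
};

struct Tally { double deposited, exited, dropped; };

static inline size_t cellIndex(const Grid& g, double px, double py, double pz) {
  int i = (int)std::floor((px - g.ox) / g.sx + 0.5);
  int j = (int)std::floor((py - g.oy) / g.sy + 0.5);
  int k = (int)std::floor((pz - g.oz) / g.sz + 0.5);
  i = i < 0 ? 0 : (i > g.nx - 1 ? g.nx - 1 : i);
  j = j < 0 ? 0 : (j > g.ny - 1 ? g.ny - 1 : j);
  k = k < 0 ? 0 : (k > g.nz - 1 ? g.nz - 1 : k);
  return (size_t)i + (size_t)g.nx * ((size_t)j + (size_t)g.ny * k);
}

// One photon: march from its entry point, split at every sample whose
// opacity is positive, deposit LC = E - LR - LT into the containing cell,
// continue the transmitted share in-line and recurse on the reflected one.
static void tracePhoton(const Grid& vol, const TFTable& tf, double* field,
                        const TraceCfg& cfg, const double o[3], const double d[3],
                        double energy, int depth, Tally& tl) {
  if (!R_finite(energy) || energy < 0)
    stop("non-finite or negative photon energy");
  double t0, t1;
  if (!boxIntersect(vol, o, d, t0, t1)) { tl.exited += energy; return; }
  if (t0 < 0) t0 = 0;
  if (t1 <= t0) { tl.exited += energy; return; }
  double E = energy;
  long nsteps = (long)std::ceil((t1 - t0) / cfg.step);
  for (long k = 0; k < nsteps; ++k) {
    double t = t0 + (k + 0.5) * cfg.step;
    if (t > t1) break;
    double p[3] = { o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2] };
    double x = samplePhys(vol, p[0], p[1], p[2]);
    double rgba[4];
    tfEval(tf, x, rgba);
    double alpha = rgba[3];
    if (alpha <= 0) continue;
    double gr[3];
    gradientPhys(vol, p[0], p[1], p[2], gr);
    double gn = std::sqrt(gr[0] * gr[0] + gr[1] * gr[1] + gr[2] * gr[2]);
    double F = 0.0;
    bool haveNormal = gn >= cfg.gradThresh;
    if (haveNormal) {
      double coshv = std::fabs((gr[0] * d[0] + gr[1] * d[1] + gr[2] * d[2]) / gn);
      coshv = clampd(coshv, 0.0, 1.0);
      double m = 1.0 - coshv;
      F = cfg.F0 + (1.0 - cfg.F0) * m * m * m * m * m;
    }
    double Fp = F < alpha ? F : alpha;   // keep the deposit non-negative
    double LT = E * (1.0 - alpha);
    double LR = E * Fp;
    double LC = E - LR - LT;             // Eq 10 form: exact conservation
    if (LC < 0) LC = 0;
    field[cellIndex(vol, p[0], p[1], p[2])] += LC;
    tl.deposited += LC;
    if (LR > 0) {
      if (haveNormal && LR >= cfg.eps && depth + 1 <= cfg.maxDepth) {
        double nx = gr[0] / gn, ny = gr[1] / gn, nz = gr[2] / gn;
        double dn = d[0] * nx + d[1] * ny + d[2] * nz;
        double r[3] = { d[0] - 2 * dn * nx, d[1] - 2 * dn * ny, d[2] - 2 * dn * nz };
        double rn = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
        if (rn > 0) {
          r[0] /= rn; r[1] /= rn; r[2] /= rn;
          tracePhoton(vol, tf, field, cfg, p, r, LR, depth + 1, tl);
        } else {
          tl.dropped += LR;
        }
      } else {
        tl.dropped += LR;
      }
    }
    E = LT;
    if (E < cfg.eps) { tl.dropped += E; return; }
  }
  tl.exited += E;
}

static Grid asGrid(const NumericVector& data, const IntegerVector& dims,
                   const NumericVector& spacing, const NumericVector& origin) {
  Grid g;
  g.d = data.begin();
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  return g;
}

static TFTable asTF(const NumericVector& tfv, const NumericMatrix& tfrgba) {
  TFTable t;
  t.v = tfv.begin(); t.rgba = tfrgba.begin(); t.n = tfv.size();
  return t;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector data, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts, bool clamp) {
  Grid g = asGrid(data, dims, spacing, origin);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    bool inside =
      p[0] >= g.ox - 0.5 * g.sx && p[0] <= g.ox + (g.nx - 0.5) * g.sx &&
      p[1] >= g.oy - 0.5 * g.sy && p[1] <= g.oy + (g.ny - 0.5) * g.sy &&
      p[2] >= g.oz - 0.5 * g.sz && p[2] <= g.oz + (g.nz - 0.5) * g.sz;
    if (!inside && !clamp) { out[i] = NA_REAL; continue; }
    out[i] = inside || clamp ? samplePhys(g, p[0], p[1], p[2]) : NA_REAL;
    if (!inside && clamp) out[i] = 0.0;  // out of the box carries no material
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gradient(NumericVector data, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix pts) {
  Grid g = asGrid(data, dims, spacing, origin);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double gr[3];
  for (int i = 0; i < n; ++i) {
    gradientPhys(g, pts(i, 0), pts(i, 1), pts(i, 2), gr);
    out(i, 0) = gr[0]; out(i, 1) = gr[1]; out(i, 2) = gr[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_tf(NumericVector tfv, NumericMatrix tfrgba, NumericVector x) {
  TFTable tf = asTF(tfv, tfrgba);
  int n = x.size();
  NumericMatrix out(n, 4);
  double rgba[4];
  for (int i = 0; i < n; ++i) {
    tfEval(tf, x[i], rgba);
    for (int c = 0; c < 4; ++c) out(i, c) = rgba[c];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_trace_photon(NumericVector data, IntegerVector dims, NumericVector spacing,
                      NumericVector origin, NumericVector tfv, NumericMatrix tfrgba,
                      NumericVector field, NumericVector porigin, NumericVector pdir,
                      double energy, double step, double eps, double F0,
                      int max_depth, double grad_thresh) {
  Grid g = asGrid(data, dims, spacing, origin);
  TFTable tf = asTF(tfv, tfrgba);
  TraceCfg cfg = { step, eps * energy, F0, max_depth, grad_thresh };
  Tally tl = { 0, 0, 0 };
  double o[3] = { porigin[0], porigin[1], porigin[2] };
  double d[3] = { pdir[0], pdir[1], pdir[2] };
  tracePhoton(g, tf, field.begin(), cfg, o, d, energy, 0, tl);
  return List::create(_["deposited"] = tl.deposited, _["exited"] = tl.exited,
                      _["dropped"] = tl.dropped);
}

// [[Rcpp::export]]
List cpp_precompute(NumericVector data, IntegerVector dims, NumericVector spacing,
                    NumericVector origin, NumericVector tfv, NumericMatrix tfrgba,
                    NumericMatrix porigins, NumericMatrix pdirs, NumericVector energies,
                    double step, double eps, double F0, int max_depth,
                    double grad_thresh) {
  Grid g = asGrid(data, dims, spacing, origin);
  TFTable tf = asTF(tfv, tfrgba);
  TraceCfg cfg = { step, eps, F0, max_depth, grad_thresh };
  size_t ncell = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector field((R_xlen_t)ncell);
  Tally tl = { 0, 0, 0 };
  int n = porigins.nrow();
  for (int i = 0; i < n; ++i) {
    double o[3] = { porigins(i, 0), porigins(i, 1), porigins(i, 2) };
    double d[3] = { pdirs(i, 0), pdirs(i, 1), pdirs(i, 2) };
    cfg.eps = eps * energies[i];
    tracePhoton(g, tf, field.begin(), cfg, o, d, energies[i], 0, tl);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["field"] = field, _["deposited"] = tl.deposited,
                      _["exited"] = tl.exited, _["dropped"] = tl.dropped);
}

// Eq 13: inverse-distance weighted mean over the 8 surrounding cell centres;
// a near-coincident cell (D < 1e-9 mm) wins outright. mode 1 = trilinear.
static double interpField(const Grid& f, double px, double py, double pz, int mode) {
  if (mode == 1) return samplePhys(f, px, py, pz);
  double u[3] = { (px - f.ox) / f.sx, (py - f.oy) / f.sy, (pz - f.oz) / f.sz };
  int n[3] = { f.nx, f.ny, f.nz };
  int i0[3], i1[3];
  for (int a = 0; a < 3; ++a) {
    double ua = clampd(u[a], 0.0, n[a] - 1.0);
    int b = (int)std::floor(ua);
    if (b > n[a] - 2) b = n[a] >= 2 ? n[a] - 2 : 0;
    i0[a] = b;
    i1[a] = n[a] >= 2 ? b + 1 : 0;
  }
  double wsum = 0, vsum = 0;
  for (int c = 0; c < 8; ++c) {
    int idx[3] = { (c & 1) ? i1[0] : i0[0], (c & 2) ? i1[1] : i0[1],
                   (c & 4) ? i1[2] : i0[2] };
    double cx = f.ox + idx[0] * f.sx, cy = f.oy + idx[1] * f.sy,
           cz = f.oz + idx[2] * f.sz;
    double dx = px - cx, dy = py - cy, dz = pz - cz;
    double D = std::sqrt(dx * dx + dy * dy + dz * dz);
    double val = voxel(f, idx[0], idx[1], idx[2]);
    if (D < 1e-9) return val;
    double w = 1.0 / D;
    wsum += w; vsum += w * val;
  }
  return vsum / wsum;
}

// [[Rcpp::export]]
NumericVector cpp_interp_ambient(NumericVector fdata, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix pts, int mode) {
  Grid f = asGrid(fdata, dims, spacing, origin);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    bool inside =
      px >= f.ox - 0.5 * f.sx && px <= f.ox + (f.nx - 0.5) * f.sx &&
      py >= f.oy - 0.5 * f.sy && py <= f.oy + (f.ny - 0.5) * f.sy &&
      pz >= f.oz - 0.5 * f.sz && pz <= f.oz + (f.nz - 0.5) * f.sz;
    out[i] = inside ? interpField(f, px, py, pz, mode) : 0.0;
  }
  return out;
}

// Fusion ray caster (Eqs 13-16): per sample with alpha > 0,
// Cfusion = C * alpha * (Linterp * dim1 + LCT * dim2), LCT = E * alpha,
// E <- E * (1 - alpha); stop when accumulated opacity reaches 1 or the ray
// leaves the box. Returns raw (unclamped) channel sums plus hit flags.
// [[Rcpp::export]]
List cpp_render(NumericVector data, IntegerVector dims, NumericVector spacing,
                NumericVector origin, NumericVector tfv, NumericMatrix tfrgba,
                NumericVector fdata, NumericMatrix rorigins, NumericMatrix rdirs,
                double step, double dim1, double dim2, int interp_mode) {
  Grid g = asGrid(data, dims, spacing, origin);
  Grid f = asGrid(fdata, dims, spacing, origin);  // co-registered with volume
  TFTable tf = asTF(tfv, tfrgba);
  int n = rorigins.nrow();
  NumericMatrix rgb(n, 3);
  LogicalVector hit(n);
  IntegerVector nsamp(n);
  for (int i = 0; i < n; ++i) {
    double o[3] = { rorigins(i, 0), rorigins(i, 1), rorigins(i, 2) };
    double d[3] = { rdirs(i, 0), rdirs(i, 1), rdirs(i, 2) };
    double t0, t1;
    double sum[3] = { 0, 0, 0 };
    bool any = false;
    int taken = 0;
    if (boxIntersect(g, o, d, t0, t1)) {
      if (t0 < 0) t0 = 0;
      double E = 1.0;     // transmitted-light energy entering the volume
      double A = 0.0;     // accumulated opacity
      long nsteps = (long)std::ceil((t1 - t0) / step);
      for (long k = 0; k < nsteps; ++k) {
        double t = t0 + (k + 0.5) * step;
        if (t > t1) break;
        ++taken;
        double p[3] = { o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2] };
        double x = samplePhys(g, p[0], p[1], p[2]);
        double rgba[4];
        tfEval(tf, x, rgba);
        double alpha = rgba[3];
        if (alpha <= 0) continue;
        any = true;
        double Li = interpField(f, p[0], p[1], p[2], interp_mode);
        double LCT = E * alpha;   // Eq 14 with F0 = 0
        E *= (1.0 - alpha);
        double w = Li * dim1 + LCT * dim2;
        sum[0] += rgba[0] * alpha * w;
        sum[1] += rgba[1] * alpha * w;
        sum[2] += rgba[2] * alpha * w;
        A += alpha;
        if (A >= 1.0) break;
      }
    }
    rgb(i, 0) = sum[0]; rgb(i, 1) = sum[1]; rgb(i, 2) = sum[2];
    hit[i] = any;
    nsamp[i] = taken;
    if ((i & 2047) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["rgb"] = rgb, _["hit"] = hit, _["nsamples"] = nsamp);
}
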