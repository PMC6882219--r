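// Core numerical kernels: streamline voxelization, orientation-field
// rasterization, trilinear field sampling, and the deterministic tracker.
// Coordinates: world mm (RAS+); voxel indices 0-based with voxel centers at
// integer indices under the grid affine. All matrices come in as 4x4 affines.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline void apply_affine(const double *m, double x, double y, double z,
                                double *out) {
  // m is a 4x4 matrix in column-major order (as R stores it)
  out[0] = m[0] * x + m[4] * y + m[8] * z + m[12];
  out[1] = m[1] * x + m[5] * y + m[9] * z + m[13];
  out[2] = m[2] * x + m[6] * y + m[10] * z + m[14];
}

// Supersampled voxel walk along one segment; calls f(linear_index) for every
// voxel hit. Sample spacing <= step_frac * min voxel size (in voxel units the
// affine is unit-free, so we supersample in world mm and convert).
template <typename F>
static void walk_segment(const double *ainv, const double *p0, const double *p1,
                         int nx, int ny, int nz, double step_mm, F f) {
  double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  int nsub = (int)std::ceil(len / step_mm);
  if (nsub < 1) nsub = 1;
  for (int s = 0; s <= nsub; s++) {
    double t = (double)s / (double)nsub;
    double w[3], v[3];
    w[0] = p0[0] + t * dx; w[1] = p0[1] + t * dy; w[2] = p0[2] + t * dz;
    apply_affine(ainv, w[0], w[1], w[2], v);
    int i = (int)std::lround(v[0]);
    int j = (int)std::lround(v[1]);
    int k = (int)std::lround(v[2]);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
    f((size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k));
  }
}

// [[Rcpp::export]]
List cpp_streamline_voxels(NumericMatrix coords, IntegerVector npts,
                           IntegerVector dim, NumericMatrix ainv,
                           double step_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<int> stamp(nvox, -1);
  const double *A = ainv.begin();
  int nsl = npts.size();
  List out(nsl);
  int row = 0;
  for (int s = 0; s < nsl; s++) {
    int np = npts[s];
    std::vector<int> hits;
    for (int q = 0; q < np - 1; q++) {
      double p0[3] = {coords(row + q, 0), coords(row + q, 1), coords(row + q, 2)};
      double p1[3] = {coords(row + q + 1, 0), coords(row + q + 1, 1),
                      coords(row + q + 1, 2)};
      walk_segment(A, p0, p1, nx, ny, nz, step_mm, [&](size_t lin) {
        if (stamp[lin] != s) {
          stamp[lin] = s;
          hits.push_back((int)(lin + 1)); // 1-based linear index for R
        }
      });
    }
    if (np == 1) { // single point still visits its voxel
      double v[3];
      apply_affine(A, coords(row, 0), coords(row, 1), coords(row, 2), v);
      int i = (int)std::lround(v[0]), j = (int)std::lround(v[1]),
          k = (int)std::lround(v[2]);
      if (i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz)
        hits.push_back((int)((size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)) + 1);
    }
    out[s] = IntegerVector(hits.begin(), hits.end());
    row += np;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_rasterize_field(NumericMatrix coords, IntegerVector npts,
                         IntegerVector dim, NumericMatrix ainv,
                         double step_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> acc(nvox * 3, 0.0);
  std::vector<int> count(nvox, 0);       // distinct streamlines per voxel
  std::vector<int> sl_stamp(nvox, -1);   // dedupe per streamline
  std::vector<int> seg_stamp(nvox, -1);  // dedupe per segment
  const double *A = ainv.begin();
  int nsl = npts.size(), row = 0, seg_id = 0;
  for (int s = 0; s < nsl; s++) {
    int np = npts[s];
    for (int q = 0; q < np - 1; q++, seg_id++) {
      double p0[3] = {coords(row + q, 0), coords(row + q, 1), coords(row + q, 2)};
      double p1[3] = {coords(row + q + 1, 0), coords(row + q + 1, 1),
                      coords(row + q + 1, 2)};
      double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
      double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (n <= 0) continue;
      d[0] /= n; d[1] /= n; d[2] /= n;
      walk_segment(A, p0, p1, nx, ny, nz, step_mm, [&](size_t lin) {
        if (sl_stamp[lin] != s) { sl_stamp[lin] = s; count[lin]++; }
        if (seg_stamp[lin] != seg_id) {
          seg_stamp[lin] = seg_id;
          double *a = &acc[lin * 3];
          double dot = a[0] * d[0] + a[1] * d[1] + a[2] * d[2];
          double sgn = (dot < 0) ? -1.0 : 1.0; // antipodal sign alignment
          a[0] += sgn * d[0]; a[1] += sgn * d[1]; a[2] += sgn * d[2];
        }
      });
    }
    row += np;
  }
  NumericVector dirs(nvox * 3);
  IntegerVector cnt(nvox);
  for (size_t v = 0; v < nvox; v++) {
    cnt[v] = count[v];
    double *a = &acc[v * 3];
    double n = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    if (n > 0 && count[v] > 0) {
      // store unit vectors in an (nvox, 3) layout matching R's array order
      dirs[v] = a[0] / n;
      dirs[v + nvox] = a[1] / n;
      dirs[v + 2 * nvox] = a[2] / n;
    }
  }
  return List::create(_["dirs"] = dirs, _["count"] = cnt);
}

struct FieldView {
  const double *dir; // (nvox, 3) layout
  const double *qa;
  int nx, ny, nz;
  size_t nvox;
};

// Trilinear interpolation of QA and of the direction field with per-corner
// sign alignment to a reference direction. Returns false when the position
// lies outside the grid's interpolation box.
static bool interp_field(const FieldView &F, const double *pvox,
                         const double *ref, double *dir_out, double *qa_out) {
  double x = pvox[0], y = pvox[1], z = pvox[2];
  if (x < 0 || y < 0 || z < 0 || x > F.nx - 1 || y > F.ny - 1 || z > F.nz - 1)
    return false;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == F.nx - 1) i0--; if (j0 == F.ny - 1) j0--; if (k0 == F.nz - 1) k0--;
  if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double q = 0, d[3] = {0, 0, 0};
  for (int c = 0; c < 8; c++) {
    int ii = i0 + (c & 1), jj = j0 + ((c >> 1) & 1), kk = k0 + ((c >> 2) & 1);
    double w = ((c & 1) ? fx : 1 - fx) * (((c >> 1) & 1) ? fy : 1 - fy) *
               (((c >> 2) & 1) ? fz : 1 - fz);
    if (w <= 0) continue;
    size_t lin = (size_t)ii + (size_t)F.nx * ((size_t)jj + (size_t)F.ny * kk);
    q += w * F.qa[lin];
    double cx = F.dir[lin], cy = F.dir[lin + F.nvox], cz = F.dir[lin + 2 * F.nvox];
    double dot = cx * ref[0] + cy * ref[1] + cz * ref[2];
    double sgn = (dot < 0) ? -1.0 : 1.0;
    d[0] += w * sgn * cx; d[1] += w * sgn * cy; d[2] += w * sgn * cz;
  }
  *qa_out = q;
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (n > 0) { d[0] /= n; d[1] /= n; d[2] /= n; }
  dir_out[0] = d[0]; dir_out[1] = d[1]; dir_out[2] = d[2];
  return true;
}

// Track one branch; appends world-mm points (excluding the seed itself) to pts.
static double track_branch(const FieldView &F, const double *ainv,
                           const double *seed_w,
                           const double *d0, double qa_thr, double cos_thr,
                           double step_mm, double smoothing, double budget_mm,
                           std::vector<double> &pts) {
  double p[3] = {seed_w[0], seed_w[1], seed_w[2]};
  double dir[3] = {d0[0], d0[1], d0[2]};
  double len = 0.0;
  while (len + step_mm <= budget_mm) {
    double pvox[3];
    apply_affine(ainv, p[0], p[1], p[2], pvox);
    double f[3], qa;
    if (!interp_field(F, pvox, dir, f, &qa)) break;
    if (qa < qa_thr) break;
    double fn = std::sqrt(f[0] * f[0] + f[1] * f[1] + f[2] * f[2]);
    if (fn <= 0) break;
    double nd[3] = {smoothing * dir[0] + (1 - smoothing) * f[0],
                    smoothing * dir[1] + (1 - smoothing) * f[1],
                    smoothing * dir[2] + (1 - smoothing) * f[2]};
    double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
    if (nn <= 0) break;
    nd[0] /= nn; nd[1] /= nn; nd[2] /= nn;
    if (nd[0] * dir[0] + nd[1] * dir[1] + nd[2] * dir[2] < cos_thr) break;
    double pn[3] = {p[0] + step_mm * nd[0], p[1] + step_mm * nd[1],
                    p[2] + step_mm * nd[2]};
    double pvn[3];
    apply_affine(ainv, pn[0], pn[1], pn[2], pvn);
    if (pvn[0] < 0 || pvn[1] < 0 || pvn[2] < 0 || pvn[0] > F.nx - 1 ||
        pvn[1] > F.ny - 1 || pvn[2] > F.nz - 1)
      break;
    p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
    dir[0] = nd[0]; dir[1] = nd[1]; dir[2] = nd[2];
    pts.push_back(p[0]); pts.push_back(p[1]); pts.push_back(p[2]);
    len += step_mm;
  }
  return len;
}

// [[Rcpp::export]]
List cpp_track(NumericVector dirfield, NumericVector qafield, IntegerVector dim,
               NumericMatrix ainv, NumericMatrix seeds,
               double qa_threshold, double angular_threshold_deg, double step_mm,
               double smoothing, double max_length_mm) {
  FieldView F;
  F.nx = dim[0]; F.ny = dim[1]; F.nz = dim[2];
  F.nvox = (size_t)F.nx * F.ny * F.nz;
  F.dir = dirfield.begin();
  F.qa = qafield.begin();
  const double *Ai = ainv.begin();
  double cos_thr = std::cos(angular_threshold_deg * M_PI / 180.0);
  int nseed = seeds.nrow();
  std::vector<double> all_pts;
  std::vector<int> npts;
  std::vector<int> seed_idx;
  for (int s = 0; s < nseed; s++) {
    double sw[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    double sv[3];
    apply_affine(Ai, sw[0], sw[1], sw[2], sv);
    double d0[3], qa0;
    double ref[3] = {1, 0, 0}; // arbitrary reference at the seed
    if (!interp_field(F, sv, ref, d0, &qa0)) continue;
    if (qa0 < qa_threshold) continue;
    double n0 = std::sqrt(d0[0] * d0[0] + d0[1] * d0[1] + d0[2] * d0[2]);
    if (n0 <= 0) continue;
    std::vector<double> fwd, bwd;
    double lf = track_branch(F, Ai, sw, d0, qa_threshold, cos_thr, step_mm,
                             smoothing, max_length_mm, fwd);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    track_branch(F, Ai, sw, d0n, qa_threshold, cos_thr, step_mm, smoothing,
                 max_length_mm - lf, bwd);
    size_t nf = fwd.size() / 3, nb = bwd.size() / 3;
    if (nf + nb + 1 < 2) continue;
    // reversed backward branch, seed, forward branch
    for (size_t q = nb; q-- > 0;) {
      all_pts.push_back(bwd[q * 3]); all_pts.push_back(bwd[q * 3 + 1]);
      all_pts.push_back(bwd[q * 3 + 2]);
    }
    all_pts.push_back(sw[0]); all_pts.push_back(sw[1]); all_pts.push_back(sw[2]);
    for (size_t q = 0; q < nf; q++) {
      all_pts.push_back(fwd[q * 3]); all_pts.push_back(fwd[q * 3 + 1]);
      all_pts.push_back(fwd[q * 3 + 2]);
    }
    npts.push_back((int)(nf + nb + 1));
    seed_idx.push_back(s + 1);
  }
  size_t ntot = all_pts.size() / 3;
  NumericMatrix coords(ntot, 3);
  for (size_t r = 0; r < ntot; r++) {
    coords(r, 0) = all_pts[r * 3];
    coords(r, 1) = all_pts[r * 3 + 1];
    coords(r, 2) = all_pts[r * 3 + 2];
  }
  return List::create(_["coords"] = coords,
                      _["npts"] = IntegerVector(npts.begin(), npts.end()),
                      _["seed"] = IntegerVector(seed_idx.begin(), seed_idx.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_trilinear_vec(NumericVector field, IntegerVector dim, int ncomp,
                                NumericMatrix pvox) {
  // field has dim (nx, ny, nz, ncomp); pvox are 0-based voxel coordinates.
  // Values outside the grid interpolate to zero.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  int n = pvox.nrow();
  NumericMatrix out(n, ncomp);
  const double *f = field.begin();
  for (int r = 0; r < n; r++) {
    double x = pvox(r, 0), y = pvox(r, 1), z = pvox(r, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
      continue; // zero outside
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1 && nx > 1) i0--;
    if (j0 == ny - 1 && ny > 1) j0--;
    if (k0 == nz - 1 && nz > 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    for (int c = 0; c < 8; c++) {
      int ii = i0 + (c & 1), jj = j0 + ((c >> 1) & 1), kk = k0 + ((c >> 2) & 1);
      if (ii >= nx || jj >= ny || kk >= nz) continue;
      double w = ((c & 1) ? fx : 1 - fx) * (((c >> 1) & 1) ? fy : 1 - fy) *
                 (((c >> 2) & 1) ? fz : 1 - fz);
      if (w <= 0) continue;
      size_t lin = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
      for (int m = 0; m < ncomp; m++) out(r, m) += w * f[lin + nvox * m];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_momentum_realize(NumericMatrix centerline, double step_mm,
                                   double smoothing) {
  // Emit a fiber by momentum flow along a centerline's tangents: directions
  // are the running blend of the previous direction with the local tangent,
  // positions integrate those directions at the given step.
  int n = centerline.nrow();
  NumericMatrix out(n, 3);
  if (n == 0) return out;
  double p[3] = {centerline(0, 0), centerline(0, 1), centerline(0, 2)};
  double d[3] = {0, 0, 0};
  out(0, 0) = p[0]; out(0, 1) = p[1]; out(0, 2) = p[2];
  for (int k = 1; k < n; k++) {
    double f[3] = {centerline(k, 0) - centerline(k - 1, 0),
                   centerline(k, 1) - centerline(k - 1, 1),
                   centerline(k, 2) - centerline(k - 1, 2)};
    double fn = std::sqrt(f[0] * f[0] + f[1] * f[1] + f[2] * f[2]);
    if (fn <= 0) { out(k, 0) = p[0]; out(k, 1) = p[1]; out(k, 2) = p[2]; continue; }
    f[0] /= fn; f[1] /= fn; f[2] /= fn;
    double nd[3];
    if (k == 1) { nd[0] = f[0]; nd[1] = f[1]; nd[2] = f[2]; }
    else {
      nd[0] = smoothing * d[0] + (1 - smoothing) * f[0];
      nd[1] = smoothing * d[1] + (1 - smoothing) * f[1];
      nd[2] = smoothing * d[2] + (1 - smoothing) * f[2];
      double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
      nd[0] /= nn; nd[1] /= nn; nd[2] /= nn;
    }
    p[0] += step_mm * nd[0]; p[1] += step_mm * nd[1]; p[2] += step_mm * nd[2];
    d[0] = nd[0]; d[1] = nd[1]; d[2] = nd[2];
    out(k, 0) = p[0]; out(k, 1) = p[1]; out(k, 2) = p[2];
  }
  return out;
}
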