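#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Voxel grids use a half-open convention: voxel (i,j,k) occupies
// [o + i*s, o + (i+1)*s) along each axis, with the (0,0,0) corner at the
// grid origin. A ray travelling exactly along a voxel face is assigned to
// the lower-index voxel by construction of the crossing test (strict <).

struct GridSpec {
  double ox, oy, oz;   // origin (corner), mm
  double sx, sy, sz;   // voxel size, mm
  int nx, ny, nz;      // voxel counts
};

// Clip parametric range of the ray p = a + t*(b-a), t in [0,1], to the grid
// bounding box. Returns false if the ray misses the box.
static bool clip_to_box(const double a[3], const double d[3],
                        const GridSpec &g, double &t0, double &t1) {
  const double lo[3] = {g.ox, g.oy, g.oz};
  const double hi[3] = {g.ox + g.nx * g.sx, g.oy + g.ny * g.sy,
                        g.oz + g.nz * g.sz};
  t0 = 0.0;
  t1 = 1.0;
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(d[ax]) < 1e-300) {
      if (a[ax] < lo[ax] || a[ax] >= hi[ax]) return false;
    } else {
      double ta = (lo[ax] - a[ax]) / d[ax];
      double tb = (hi[ax] - a[ax]) / d[ax];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 >= t1) return false;
    }
  }
  return t0 < t1;
}

// March the clipped ray through the grid, invoking f(i, j, k, seg_mm) for
// each traversed voxel. Amanatides-Woo style stepping on Siddon's
// parametrization.
template <typename F>
static void march(const double a[3], const double b[3], const GridSpec &g,
                  F f) {
  double d[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double t0, t1;
  if (!clip_to_box(a, d, g, t0, t1)) return;
  const double ray_len = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (ray_len <= 0.0) return;

  const double o[3] = {g.ox, g.oy, g.oz};
  const double s[3] = {g.sx, g.sy, g.sz};
  const int n[3] = {g.nx, g.ny, g.nz};

  // entry point, nudged inside to land in a well-defined voxel
  double tcur = t0;
  double p[3];
  int idx[3];
  for (int ax = 0; ax < 3; ++ax) {
    p[ax] = a[ax] + tcur * d[ax];
    double fi = (p[ax] - o[ax]) / s[ax];
    int i = (int)std::floor(fi);
    if (i < 0) i = 0;
    if (i >= n[ax]) i = n[ax] - 1;
    idx[ax] = i;
  }
  int step[3];
  double tdelta[3], tmax[3];
  for (int ax = 0; ax < 3; ++ax) {
    if (d[ax] > 0) {
      step[ax] = 1;
      tdelta[ax] = s[ax] / d[ax];
      tmax[ax] = ((o[ax] + (idx[ax] + 1) * s[ax]) - a[ax]) / d[ax];
    } else if (d[ax] < 0) {
      step[ax] = -1;
      tdelta[ax] = -s[ax] / d[ax];
      tmax[ax] = ((o[ax] + idx[ax] * s[ax]) - a[ax]) / d[ax];
    } else {
      step[ax] = 0;
      tdelta[ax] = R_PosInf;
      tmax[ax] = R_PosInf;
    }
  }
  while (tcur < t1 - 1e-15) {
    int ax = 0;
    if (tmax[1] < tmax[ax]) ax = 1;
    if (tmax[2] < tmax[ax]) ax = 2;
    double tnext = tmax[ax];
    if (tnext > t1) tnext = t1;
    double seg = (tnext - tcur) * ray_len;
    if (seg > 0) f(idx[0], idx[1], idx[2], seg);
    tcur = tnext;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= n[ax]) break;
    tmax[ax] += tdelta[ax];
  }
}

static GridSpec as_grid(NumericVector origin, NumericVector voxel,
                        IntegerVector dims) {
  GridSpec g;
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.sx = voxel[0];  g.sy = voxel[1];  g.sz = voxel[2];
  g.nx = dims[0];   g.ny = dims[1];   g.nz = dims[2];
  return g;
}

// [[Rcpp::export]]
List siddon_trace_cpp(NumericVector src, NumericVector dst,
                      NumericVector origin, NumericVector voxel,
                      IntegerVector dims) {
  GridSpec g = as_grid(origin, voxel, dims);
  double a[3] = {src[0], src[1], src[2]};
  double b[3] = {dst[0], dst[1], dst[2]};
  std::vector<int> vi, vj, vk;
  std::vector<double> vl;
  march(a, b, g, [&](int i, int j, int k, double seg) {
    vi.push_back(i + 1);
    vj.push_back(j + 1);
    vk.push_back(k + 1);
    vl.push_back(seg);
  });
  int m = (int)vl.size();
  IntegerMatrix idx(m, 3);
  NumericVector len(m);
  for (int r = 0; r < m; ++r) {
    idx(r, 0) = vi[r];
    idx(r, 1) = vj[r];
    idx(r, 2) = vk[r];
    len[r] = vl[r];
  }
  return List::create(_["idx"] = idx, _["len"] = len);
}

// Per-ray material path lengths: for each detector point, the total
// intersection length (mm) with voxels of each label. labels are 0-based
// material codes laid out in R's column-major array order.
// [[Rcpp::export]]
NumericMatrix forward_paths_cpp(IntegerVector labels, IntegerVector dims,
                                NumericVector origin, NumericVector voxel,
                                NumericVector src, NumericMatrix det_pts,
                                int n_materials) {
  GridSpec g = as_grid(origin, voxel, dims);
  const int npix = det_pts.nrow();
  NumericMatrix out(npix, n_materials);
  const int nx = g.nx, ny = g.ny;
  double a[3] = {src[0], src[1], src[2]};
  for (int p = 0; p < npix; ++p) {
    double b[3] = {det_pts(p, 0), det_pts(p, 1), det_pts(p, 2)};
    march(a, b, g, [&](int i, int j, int k, double seg) {
      int lab = labels[i + nx * (j + (R_xlen_t)ny * k)];
      if (lab >= 0 && lab < n_materials) out(p, lab) += seg;
    });
  }
  return out;
}

// Voxel-driven backprojection onto a stationary detector in the z = 0
// plane. proj holds filtered line integrals as an nu x nv x P array;
// sources is P x 3. Detector pixel (u, v) centre sits at
// (det0[0] + u*pitch[0], det0[1] + v*pitch[1], 0), 0-based u, v.
// [[Rcpp::export]]
NumericVector backproject_cpp(NumericVector proj, IntegerVector proj_dims,
                              NumericMatrix sources, NumericVector det0,
                              NumericVector pitch, NumericVector out_origin,
                              NumericVector out_voxel, IntegerVector out_dims) {
  const int nu = proj_dims[0], nv = proj_dims[1], P = proj_dims[2];
  const int nx = out_dims[0], ny = out_dims[1], nz = out_dims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  vol.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double wview = 1.0 / P;
  for (int view = 0; view < P; ++view) {
    const double sx = sources(view, 0), sy = sources(view, 1),
                 sz = sources(view, 2);
    const double *pv = &proj[(R_xlen_t)view * nu * nv];
    R_xlen_t vidx = 0;
    for (int k = 0; k < nz; ++k) {
      double z = out_origin[2] + (k + 0.5) * out_voxel[2];
      double t = sz / (sz - z);
      for (int j = 0; j < ny; ++j) {
        double y = out_origin[1] + (j + 0.5) * out_voxel[1];
        double py = sy + (y - sy) * t;
        double v = (py - det0[1]) / pitch[1];
        for (int i = 0; i < nx; ++i, ++vidx) {
          double x = out_origin[0] + (i + 0.5) * out_voxel[0];
          double px = sx + (x - sx) * t;
          double u = (px - det0[0]) / pitch[0];
          if (u < 0 || u > nu - 1 || v < 0 || v > nv - 1) continue;
          int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
          if (u0 >= nu - 1) u0 = nu - 2;
          if (v0 >= nv - 1) v0 = nv - 2;
          double fu = u - u0, fv = v - v0;
          double val =
              (1 - fu) * (1 - fv) * pv[u0 + nu * v0] +
              fu * (1 - fv) * pv[u0 + 1 + nu * v0] +
              (1 - fu) * fv * pv[u0 + nu * (v0 + 1)] +
              fu * fv * pv[u0 + 1 + nu * (v0 + 1)];
          vol[vidx] += wview * val;
        }
      }
    }
  }
  return vol;
}
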