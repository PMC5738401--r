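// Numerical core: exact Euclidean distance transforms, trilinear sampling of
// scalar grids, Newton projection onto implicit surfaces, Parzen particle
// interactions for the correspondence optimizer, marching-tetrahedra surface
// extraction, and a 26-connectivity component counter.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Felzenszwalb & Huttenlocher 1D squared distance transform, anisotropic
// sample positions x_q = q*h.  f holds squared distances (INF if no site).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  int k = -1;  // hull over parabolas with finite f only
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + q * q * h * h) - (f[p] + p * p * h * h)) /
          (2.0 * h * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double x = q * h;
    while (z[j + 1] < x) ++j;
    double dx = x - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
}

// squared EDT of `sites` (TRUE voxels are distance 0) on an anisotropic grid
static std::vector<double> edt_sq(const std::vector<char>& site,
                                  const int* dim, const double* sp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> d(ntot);
  for (size_t i = 0; i < ntot; ++i) d[i] = site[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t off = (size_t)nx * (j + (size_t)ny * k);
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = d[off + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, g, nx, sp[0], v, z);
      for (int i = 0; i < nx; ++i) d[off + i] = g[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t off = i + (size_t)nx * ny * k;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = d[off + (size_t)nx * j]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, g, ny, sp[1], v, z);
      for (int j = 0; j < ny; ++j) d[off + (size_t)nx * j] = g[j];
    }
  // pass along z (stride nx*ny)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t off = i + (size_t)nx * j;
      size_t str = (size_t)nx * ny;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = d[off + str * k]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, g, nz, sp[2], v, z);
      for (int k = 0; k < nz; ++k) d[off + str * k] = g[k];
    }
  return d;
}

// [[Rcpp::export(name = ".signed_edt")]]
NumericVector signed_edt(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int d3[3] = {dim[0], dim[1], dim[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  size_t ntot = (size_t)d3[0] * d3[1] * d3[2];
  std::vector<char> fg(ntot), bg(ntot);
  for (size_t i = 0; i < ntot; ++i) { fg[i] = mask[i] != 0; bg[i] = mask[i] == 0; }
  std::vector<double> dfg = edt_sq(fg, d3, sp);  // distance to foreground
  std::vector<double> dbg = edt_sq(bg, d3, sp);  // distance to background
  NumericVector phi(ntot);
  for (size_t i = 0; i < ntot; ++i)
    phi[i] = fg[i] ? -std::sqrt(dbg[i]) : std::sqrt(dfg[i]);
  phi.attr("dim") = dim;
  return phi;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing, reflected boundaries; sigma in voxel units
// [[Rcpp::export(name = ".gauss_smooth3d")]]
NumericVector gauss_smooth3d(NumericVector a, IntegerVector dim,
                             NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> src(a.begin(), a.end()), dst(ntot);
  int dims[3] = {nx, ny, nz};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) { ker[t + rad] = std::exp(-0.5 * t * t / (s * s)); sum += ker[t + rad]; }
    for (double& kv : ker) kv /= sum;

    size_t stride = 1;
    for (int ax = 0; ax < axis; ++ax) stride *= dims[ax];
    int n = dims[axis];

    for (size_t base = 0; base < ntot; ++base) {
      // decompose index; process only line starts
      size_t idx = base;
      int coord[3];
      coord[0] = idx % nx; idx /= nx;
      coord[1] = idx % ny; idx /= ny;
      coord[2] = idx;
      if (coord[axis] != 0) continue;
      for (int q = 0; q < n; ++q) {
        double acc = 0;
        for (int t = -rad; t <= rad; ++t) {
          int qq = q + t;
          if (qq < 0) qq = -qq - 1;          // reflect
          if (qq >= n) qq = 2 * n - qq - 1;
          acc += ker[t + rad] * src[base + stride * (size_t)qq];
        }
        dst[base + stride * (size_t)q] = acc;
      }
    }
    std::swap(src, dst);
  }
  NumericVector out(src.begin(), src.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// central-difference gradient grids of a scalar field (one-sided at borders)
// [[Rcpp::export(name = ".gradient_grids")]]
List gradient_grids(NumericVector phi, IntegerVector dim,
                    NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  NumericVector gx(ntot), gy(ntot), gz(ntot);
  size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + sy * j + sz * k;
        int il = std::max(i - 1, 0), ir = std::min(i + 1, nx - 1);
        int jl = std::max(j - 1, 0), jr = std::min(j + 1, ny - 1);
        int kl = std::max(k - 1, 0), kr = std::min(k + 1, nz - 1);
        gx[id] = (phi[ir + sy * j + sz * k] - phi[il + sy * j + sz * k]) / ((ir - il) * spacing[0]);
        gy[id] = (phi[i + sy * jr + sz * k] - phi[i + sy * jl + sz * k]) / ((jr - jl) * spacing[1]);
        gz[id] = (phi[i + sy * j + sz * kr] - phi[i + sy * j + sz * kl]) / ((kr - kl) * spacing[2]);
      }
  gx.attr("dim") = dim; gy.attr("dim") = dim; gz.attr("dim") = dim;
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// trilinear sample of one grid at one (already clamped) index-space point
static double tri(const double* a, const int* dim, double u, double v, double w) {
  int i = (int)std::floor(u), j = (int)std::floor(v), k = (int)std::floor(w);
  if (i > dim[0] - 2) i = dim[0] - 2;
  if (j > dim[1] - 2) j = dim[1] - 2;
  if (k > dim[2] - 2) k = dim[2] - 2;
  if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
  double fu = u - i, fv = v - j, fw = w - k;
  size_t sy = dim[0], sz = (size_t)dim[0] * dim[1];
  size_t id = i + sy * j + sz * k;
  double c00 = a[id] * (1 - fu) + a[id + 1] * fu;
  double c10 = a[id + sy] * (1 - fu) + a[id + sy + 1] * fu;
  double c01 = a[id + sz] * (1 - fu) + a[id + sz + 1] * fu;
  double c11 = a[id + sy + sz] * (1 - fu) + a[id + sy + sz + 1] * fu;
  double c0 = c00 * (1 - fv) + c10 * fv;
  double c1 = c01 * (1 - fv) + c11 * fv;
  return c0 * (1 - fw) + c1 * fw;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export(name = ".interp3")]]
NumericVector interp3(NumericVector arr, IntegerVector dim,
                      NumericVector spacing, NumericVector origin,
                      NumericMatrix pts) {
  int d3[3] = {dim[0], dim[1], dim[2]};
  int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double u = clampd((pts(p, 0) - origin[0]) / spacing[0], 0.0, d3[0] - 1.0);
    double v = clampd((pts(p, 1) - origin[1]) / spacing[1], 0.0, d3[1] - 1.0);
    double w = clampd((pts(p, 2) - origin[2]) / spacing[2], 0.0, d3[2] - 1.0);
    out[p] = tri(REAL(arr), d3, u, v, w);
  }
  return out;
}

// Newton projection x <- x - phi * grad / |grad|^2 onto the zero level set
// [[Rcpp::export(name = ".project_newton")]]
List project_newton(NumericVector phi, NumericVector gx, NumericVector gy,
                    NumericVector gz, IntegerVector dim, NumericVector spacing,
                    NumericVector origin, NumericMatrix pts, double tol,
                    int maxit) {
  int d3[3] = {dim[0], dim[1], dim[2]};
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = origin[a]; hi[a] = origin[a] + spacing[a] * (d3[a] - 1); }
  int n = pts.nrow();
  NumericMatrix out(clone(pts));
  NumericVector resid(n);
  LogicalVector conv(n);
  double hmin = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  for (int p = 0; p < n; ++p) {
    double x[3] = {out(p, 0), out(p, 1), out(p, 2)};
    double val = 0; bool ok = false;
    int nudge = 0;
    for (int it = 0; it < maxit; ++it) {
      double u = clampd((x[0] - lo[0]) / spacing[0], 0.0, d3[0] - 1.0);
      double v = clampd((x[1] - lo[1]) / spacing[1], 0.0, d3[1] - 1.0);
      double w = clampd((x[2] - lo[2]) / spacing[2], 0.0, d3[2] - 1.0);
      val = tri(REAL(phi), d3, u, v, w);
      if (std::fabs(val) <= tol) { ok = true; break; }
      double g[3] = {tri(REAL(gx), d3, u, v, w), tri(REAL(gy), d3, u, v, w),
                     tri(REAL(gz), d3, u, v, w)};
      double g2 = g[0] * g[0] + g[1] * g[1] + g[2] * g[2];
      if (g2 < 1e-12) {
        // degenerate gradient (e.g. shape center): deterministic axis nudge
        x[nudge % 3] += hmin * (1 + nudge / 3);
        ++nudge;
        continue;
      }
      double step = val / g2;
      for (int a = 0; a < 3; ++a) x[a] = clampd(x[a] - step * g[a], lo[a], hi[a]);
    }
    out(p, 0) = x[0]; out(p, 1) = x[1]; out(p, 2) = x[2];
    resid[p] = val; conv[p] = ok;
  }
  return List::create(_["points"] = out, _["residual"] = resid,
                      _["converged"] = conv);
}

// ---------------------------------------------------------------------------
// per-particle Gaussian kernel width: bisect sigma so that the weighted
// neighbor count sum_j exp(-d^2/(2 s^2)) hits `target`
// [[Rcpp::export(name = ".adapt_sigma")]]
NumericVector adapt_sigma(NumericMatrix pts, double target, double lo,
                          double hi, double nn_cap = 1.3) {
  int k = pts.nrow();
  NumericVector sig(k);
  std::vector<double> d2((size_t)k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1),
             dz = pts(i, 2) - pts(j, 2);
      d2[(size_t)k * i + j] = dx * dx + dy * dy + dz * dz;
    }
  for (int i = 0; i < k; ++i) {
    double a = lo, b = hi;
    double tgt = std::min(target, 0.5 * (k - 1));
    double nn2 = INF;
    for (int j = 0; j < k; ++j) {
      if (j != i && d2[(size_t)k * i + j] < nn2) nn2 = d2[(size_t)k * i + j];
    }
    for (int it = 0; it < 30; ++it) {
      double s = std::sqrt(a * b);
      double W = 0;
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        W += std::exp(-0.5 * d2[(size_t)k * i + j] / (s * s));
      }
      if (W < tgt) a = s; else b = s;
    }
    sig[i] = std::sqrt(a * b);
    // keep the kernel local: during post-split transients the neighbor-count
    // criterion inflates sigma past the local spacing, flattening the
    // repulsion; cap at a multiple of the nearest-neighbor distance
    if (nn2 < INF && nn_cap > 0) {
      double cap = nn_cap * std::sqrt(nn2);
      if (sig[i] > cap) sig[i] = cap;
      if (sig[i] < cap * 1e-3) sig[i] = cap * 1e-3;
    }
  }
  return sig;
}

// Parzen crowding term E = sum_i log( S_i / (k-1) ),
// S_i = sum_{j != i} exp(-|x_i-x_j|^2 / (2 sigma_i^2)); exact gradient,
// per-particle gradient norm capped at gmax (coincident-particle guard).
// [[Rcpp::export(name = ".parzen_terms")]]
List parzen_terms(NumericMatrix pts, NumericVector sigma, double gmax) {
  int k = pts.nrow();
  std::vector<double> S(k, 0.0);
  std::vector<double> K((size_t)k * k, 0.0);  // K[i*k+j] = K_i(j)
  for (int i = 0; i < k; ++i) {
    double s2 = sigma[i] * sigma[i];
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1),
             dz = pts(i, 2) - pts(j, 2);
      double kv = std::exp(-0.5 * (dx * dx + dy * dy + dz * dz) / s2);
      K[(size_t)k * i + j] = kv;
      S[i] += kv;
    }
    if (S[i] < 1e-300) S[i] = 1e-300;
  }
  double E = 0;
  for (int i = 0; i < k; ++i) E += std::log(S[i] / (k - 1));
  NumericMatrix G(k, 3);
  for (int p = 0; p < k; ++p) {
    double g[3] = {0, 0, 0};
    for (int j = 0; j < k; ++j) {
      if (j == p) continue;
      double c = K[(size_t)k * p + j] / (S[p] * sigma[p] * sigma[p]) +
                 K[(size_t)k * j + p] / (S[j] * sigma[j] * sigma[j]);
      g[0] -= c * (pts(p, 0) - pts(j, 0));
      g[1] -= c * (pts(p, 1) - pts(j, 1));
      g[2] -= c * (pts(p, 2) - pts(j, 2));
    }
    double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
    if (gn > gmax) for (double& gc : g) gc *= gmax / gn;
    G(p, 0) = g[0]; G(p, 1) = g[1]; G(p, 2) = g[2];
  }
  return List::create(_["value"] = E, _["grad"] = G);
}

// ---------------------------------------------------------------------------
// marching tetrahedra on the zero level set (Kuhn 6-tet cube subdivision,
// translation-consistent, hence watertight); inside = phi < 0
// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector phi, IntegerVector dim, NumericVector spacing,
                NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sy = nx, sz = (size_t)nx * ny;
  const double* f = REAL(phi);

  // Kuhn subdivision: paths 0 -> +e_p1 -> +e_p2 -> (1,1,1)
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> V;
  std::vector<int> F;
  size_t ntot = (size_t)nx * ny * nz;

  auto corner_id = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  auto val_of = [&](uint64_t id) -> double {
    double v = f[id];
    if (std::fabs(v) < 1e-12) v = -1e-12;
    return v;
  };
  auto pos_of = [&](uint64_t id, double* p) {
    int i = id % nx; uint64_t r = id / nx;
    int j = r % ny; int k = r / ny;
    p[0] = origin[0] + spacing[0] * i;
    p[1] = origin[1] + spacing[1] * j;
    p[2] = origin[2] + spacing[2] * k;
  };
  auto edge_pt = [&](uint64_t a, uint64_t b) -> int {
    uint64_t u = std::min(a, b), w = std::max(a, b);
    uint64_t key = u * ntot + w;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = val_of(a), vb = val_of(b);
    double t = va / (va - vb);
    double pa[3], pb[3];
    pos_of(a, pa); pos_of(b, pb);
    int id = (int)(V.size() / 3);
    for (int c = 0; c < 3; ++c) V.push_back(pa[c] + t * (pb[c] - pa[c]));
    edge_vertex[key] = id;
    return id;
  };
  auto vpos = [&](int vid, double* p) {
    p[0] = V[3 * vid]; p[1] = V[3 * vid + 1]; p[2] = V[3 * vid + 2];
  };
  // append triangle, oriented so its normal points away from `inpt`
  auto add_tri = [&](int a, int b, int c, const double* inpt) {
    double pa[3], pb[3], pc[3];
    vpos(a, pa); vpos(b, pb); vpos(c, pc);
    double u[3], v[3], nrm[3], cen[3];
    for (int t = 0; t < 3; ++t) {
      u[t] = pb[t] - pa[t]; v[t] = pc[t] - pa[t];
      cen[t] = (pa[t] + pb[t] + pc[t]) / 3.0 - inpt[t];
    }
    nrm[0] = u[1] * v[2] - u[2] * v[1];
    nrm[1] = u[2] * v[0] - u[0] * v[2];
    nrm[2] = u[0] * v[1] - u[1] * v[0];
    double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
    if (dot >= 0) { F.push_back(a); F.push_back(b); F.push_back(c); }
    else { F.push_back(a); F.push_back(c); F.push_back(b); }
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject: all 8 corners same sign
        double v000 = val_of(corner_id(i, j, k));
        bool mixed = false;
        for (int b = 1; b < 8; ++b) {
          uint64_t cid = corner_id(i + (b & 1), j + ((b >> 1) & 1), k + ((b >> 2) & 1));
          if ((val_of(cid) < 0) != (v000 < 0)) { mixed = true; break; }
        }
        if (!mixed) continue;
        for (int t = 0; t < 6; ++t) {
          int off[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
          off[1][perms[t][0]] = 1;
          off[2][perms[t][0]] = 1; off[2][perms[t][1]] = 1;
          uint64_t cid[4];
          double val[4];
          for (int c = 0; c < 4; ++c) {
            cid[c] = corner_id(i + off[c][0], j + off[c][1], k + off[c][2]);
            val[c] = val_of(cid[c]);
          }
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[c] < 0) in_idx[ni++] = c; else out_idx[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1) {
            double ip[3]; pos_of(cid[in_idx[0]], ip);
            int a = edge_pt(cid[in_idx[0]], cid[out_idx[0]]);
            int b = edge_pt(cid[in_idx[0]], cid[out_idx[1]]);
            int c = edge_pt(cid[in_idx[0]], cid[out_idx[2]]);
            add_tri(a, b, c, ip);
          } else if (ni == 3) {
            double ip[3] = {0, 0, 0}, tmp[3];
            for (int q = 0; q < 3; ++q) {
              pos_of(cid[in_idx[q]], tmp);
              for (int c = 0; c < 3; ++c) ip[c] += tmp[c] / 3.0;
            }
            int a = edge_pt(cid[out_idx[0]], cid[in_idx[0]]);
            int b = edge_pt(cid[out_idx[0]], cid[in_idx[1]]);
            int c = edge_pt(cid[out_idx[0]], cid[in_idx[2]]);
            add_tri(a, b, c, ip);
          } else {  // 2 in, 2 out: quad
            double ip[3] = {0, 0, 0}, tmp[3];
            for (int q = 0; q < 2; ++q) {
              pos_of(cid[in_idx[q]], tmp);
              for (int c = 0; c < 3; ++c) ip[c] += tmp[c] / 2.0;
            }
            int e1 = edge_pt(cid[in_idx[0]], cid[out_idx[0]]);
            int e2 = edge_pt(cid[in_idx[0]], cid[out_idx[1]]);
            int e3 = edge_pt(cid[in_idx[1]], cid[out_idx[1]]);
            int e4 = edge_pt(cid[in_idx[1]], cid[out_idx[0]]);
            add_tri(e1, e2, e3, ip);
            add_tri(e1, e3, e4, ip);
          }
        }
      }

  int nv = (int)(V.size() / 3), nf = (int)(F.size() / 3);
  NumericMatrix verts(nv, 3);
  IntegerMatrix faces(nf, 3);
  for (int q = 0; q < nv; ++q)
    for (int c = 0; c < 3; ++c) verts(q, c) = V[3 * q + c];
  for (int q = 0; q < nf; ++q)
    for (int c = 0; c < 3; ++c) faces(q, c) = F[3 * q + c] + 1;  // 1-based
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// number of 26-connected foreground components
// [[Rcpp::export(name = ".count_components26")]]
int count_components26(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<char> seen(ntot, 0);
  std::vector<size_t> stack;
  int ncomp = 0;
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s] || seen[s]) continue;
    ++ncomp;
    seen[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int i = cur % nx; size_t r = cur / nx;
      int j = r % ny; int k = r / ny;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t nb = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[nb] && !seen[nb]) { seen[nb] = 1; stack.push_back(nb); }
          }
    }
  }
  return ncomp;
}

// ---------------------------------------------------------------------------
// signed distance to the zero level set of a smooth field psi (negative
// inside): subvoxel seeds d = |psi|/|grad psi| at sign-change voxels, then
// fast-sweeping eikonal solve (Zhao 2004), 8 sweep directions x n_passes.
// [[Rcpp::export(name = ".eikonal_sdf")]]
NumericVector eikonal_sdf(NumericVector psi, IntegerVector dim,
                          NumericVector spacing, int n_passes = 3) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t sy = nx, sz = (size_t)nx * ny, ntot = (size_t)nx * ny * nz;
  const double* p = REAL(psi);
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  double hmax = std::max(hx, std::max(hy, hz));
  double hmin = std::min(hx, std::min(hy, hz));

  std::vector<double> d(ntot, INF);
  std::vector<char> frozen(ntot, 0);

  // seeds: voxels with a 6-neighbor sign change
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + sy * j + sz * k;
        bool neg = p[id] < 0;
        bool cross = false;
        if (i > 0 && ((p[id - 1] < 0) != neg)) cross = true;
        if (!cross && i + 1 < nx && ((p[id + 1] < 0) != neg)) cross = true;
        if (!cross && j > 0 && ((p[id - sy] < 0) != neg)) cross = true;
        if (!cross && j + 1 < ny && ((p[id + sy] < 0) != neg)) cross = true;
        if (!cross && k > 0 && ((p[id - sz] < 0) != neg)) cross = true;
        if (!cross && k + 1 < nz && ((p[id + sz] < 0) != neg)) cross = true;
        if (!cross) continue;
        int il = std::max(i - 1, 0), ir = std::min(i + 1, nx - 1);
        int jl = std::max(j - 1, 0), jr = std::min(j + 1, ny - 1);
        int kl = std::max(k - 1, 0), kr = std::min(k + 1, nz - 1);
        double gx = (p[ir + sy * j + sz * k] - p[il + sy * j + sz * k]) / ((ir - il) * hx);
        double gy = (p[i + sy * jr + sz * k] - p[i + sy * jl + sz * k]) / ((jr - jl) * hy);
        double gz = (p[i + sy * j + sz * kr] - p[i + sy * j + sz * kl]) / ((kr - kl) * hz);
        double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
        double dist = std::fabs(p[id]) / std::max(gn, 1e-12);
        if (dist > 1.74 * hmax) dist = 1.74 * hmax;  // seed sanity clamp
        if (dist < 1e-4 * hmin) dist = 1e-4 * hmin;
        d[id] = dist;
        frozen[id] = 1;
      }

  // eikonal update from axis-neighbor minima
  auto solve_at = [&](size_t id, int i, int j, int k) {
    double n_ax[3], h_ax[3];
    int m = 0;
    double a = INF;
    if (i > 0) a = d[id - 1];
    if (i + 1 < nx && d[id + 1] < a) a = d[id + 1];
    if (a < INF) { n_ax[m] = a; h_ax[m] = hx; ++m; }
    a = INF;
    if (j > 0) a = d[id - sy];
    if (j + 1 < ny && d[id + sy] < a) a = d[id + sy];
    if (a < INF) { n_ax[m] = a; h_ax[m] = hy; ++m; }
    a = INF;
    if (k > 0) a = d[id - sz];
    if (k + 1 < nz && d[id + sz] < a) a = d[id + sz];
    if (a < INF) { n_ax[m] = a; h_ax[m] = hz; ++m; }
    if (m == 0) return;
    // sort ascending by n_ax
    for (int u = 1; u < m; ++u)
      for (int v = u; v > 0 && n_ax[v] < n_ax[v - 1]; --v) {
        std::swap(n_ax[v], n_ax[v - 1]);
        std::swap(h_ax[v], h_ax[v - 1]);
      }
    double x = n_ax[0] + h_ax[0];
    for (int used = 2; used <= m; ++used) {
      if (x <= n_ax[used - 1]) break;
      double A = 0, B = 0, C = -1;
      for (int u = 0; u < used; ++u) {
        double ih2 = 1.0 / (h_ax[u] * h_ax[u]);
        A += ih2;
        B -= 2.0 * n_ax[u] * ih2;
        C += n_ax[u] * n_ax[u] * ih2;
      }
      double disc = B * B - 4 * A * C;
      if (disc < 0) break;
      x = (-B + std::sqrt(disc)) / (2 * A);
    }
    if (x < d[id]) d[id] = x;
  };

  for (int pass = 0; pass < n_passes; ++pass)
    for (int sweep = 0; sweep < 8; ++sweep) {
      int di = (sweep & 1) ? -1 : 1;
      int dj = (sweep & 2) ? -1 : 1;
      int dk = (sweep & 4) ? -1 : 1;
      for (int k = dk > 0 ? 0 : nz - 1; k >= 0 && k < nz; k += dk)
        for (int j = dj > 0 ? 0 : ny - 1; j >= 0 && j < ny; j += dj)
          for (int i = di > 0 ? 0 : nx - 1; i >= 0 && i < nx; i += di) {
            size_t id = i + sy * j + sz * k;
            // seeds also relax (min-only), enforcing the Lipschitz bound on
            // over-estimated first-order seed values
            solve_at(id, i, j, k);
          }
    }

  NumericVector out(ntot);
  for (size_t id = 0; id < ntot; ++id)
    out[id] = (p[id] < 0) ? -d[id] : d[id];
  out.attr("dim") = dim;
  return out;
}

// interpolate three grids (e.g. gradient components) at once
// [[Rcpp::export(name = ".interp3v")]]
NumericMatrix interp3v(NumericVector ax, NumericVector ay, NumericVector az,
                       IntegerVector dim, NumericVector spacing,
                       NumericVector origin, NumericMatrix pts) {
  int d3[3] = {dim[0], dim[1], dim[2]};
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    double u = clampd((pts(p, 0) - origin[0]) / spacing[0], 0.0, d3[0] - 1.0);
    double v = clampd((pts(p, 1) - origin[1]) / spacing[1], 0.0, d3[1] - 1.0);
    double w = clampd((pts(p, 2) - origin[2]) / spacing[2], 0.0, d3[2] - 1.0);
    out(p, 0) = tri(REAL(ax), d3, u, v, w);
    out(p, 1) = tri(REAL(ay), d3, u, v, w);
    out(p, 2) = tri(REAL(az), d3, u, v, w);
  }
  return out;
}
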