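#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Volumes are passed as flat vectors in R's column-major order with
// dimensions (nx, ny, nz); 2D inputs use nz = 1. All distances in mm.

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Separable kernel convolution with renormalized (mass-preserving) boundaries:
// a constant input maps exactly to the same constant.
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double> &x, int nx, int ny, int nz,
                      const std::vector<double> &k, int axis) {
  int nk = (int)k.size();
  if (nk <= 1) return;
  int c = nk / 2; // kernel centre (odd kernels expected)
  int dims[3] = {nx, ny, nz};
  int n = dims[axis];
  std::vector<double> line(n), out(n);
  int stride = (axis == 0) ? 1 : (axis == 1 ? nx : nx * ny);
  // iterate over all lines along `axis`
  int n1, n2, s1, s2;
  if (axis == 0)      { n1 = ny; n2 = nz; s1 = nx; s2 = nx * ny; }
  else if (axis == 1) { n1 = nx; n2 = nz; s1 = 1;  s2 = nx * ny; }
  else                { n1 = nx; n2 = ny; s1 = 1;  s2 = nx; }
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      int base = j1 * s1 + j2 * s2;
      for (int i = 0; i < n; ++i) line[i] = x[base + i * stride];
      int iLo = std::min(c, n), iHi = std::max(n - (nk - 1 - c), iLo);
      for (int i = 0; i < iLo; ++i) { // left boundary: renormalize
        double acc = 0.0, wsum = 0.0;
        int lo = c - i, hi = std::min(nk, n + c - i);
        for (int t = lo; t < hi; ++t) { acc += k[t] * line[i + t - c]; wsum += k[t]; }
        out[i] = (wsum > 0.0) ? acc / wsum : 0.0;
      }
      for (int i = iLo; i < iHi; ++i) { // interior: kernel sums to 1
        double acc = 0.0;
        const double *p = &line[i - c];
        for (int t = 0; t < nk; ++t) acc += k[t] * p[t];
        out[i] = acc;
      }
      for (int i = iHi; i < n; ++i) { // right boundary: renormalize
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(0, c - i), hi = n + c - i;
        for (int t = lo; t < hi; ++t) { acc += k[t] * line[i + t - c]; wsum += k[t]; }
        out[i] = (wsum > 0.0) ? acc / wsum : 0.0;
      }
      for (int i = 0; i < n; ++i) x[base + i * stride] = out[i];
    }
  }
}

// [[Rcpp::export(name = ".cpp_sepconv")]]
NumericVector cpp_sepconv(NumericVector x, IntegerVector dims, List kernels) {
  int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
      nz = dims.size() > 2 ? dims[2] : 1;
  std::vector<double> buf(x.begin(), x.end());
  for (int a = 0; a < (int)kernels.size() && a < 3; ++a) {
    NumericVector kv = kernels[a];
    std::vector<double> k(kv.begin(), kv.end());
    conv_axis(buf, nx, ny, nz, k, a);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = x.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), anisotropic spacing supported.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, int n, double h,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  double h2 = h * h;
  int k = -1; // index of the rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // infinite sources never contribute
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
  } else {
    int j = 0;
    for (int q = 0; q < n; ++q) {
      while (z[j + 1] < q) ++j;
      d[q] = h2 * (double)(q - v[j]) * (q - v[j]) + f[v[j]];
    }
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// squared distance (mm^2) to the nearest seed voxel centre (seed != 0)
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector seed, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
      nz = dims.size() > 2 ? dims[2] : 1;
  int n = nx * ny * nz;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = seed[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  double hx = spacing[0], hy = spacing.size() > 1 ? spacing[1] : 1.0,
         hz = spacing.size() > 2 ? spacing[2] : 1.0;
  // axis x
  for (int k3 = 0; k3 < nz; ++k3)
    for (int k2 = 0; k2 < ny; ++k2) {
      int base = k2 * nx + k3 * nx * ny;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, nx, hx, d, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = f[i];
    }
  // axis y
  if (ny > 1)
    for (int k3 = 0; k3 < nz; ++k3)
      for (int k1 = 0; k1 < nx; ++k1) {
        int base = k1 + k3 * nx * ny;
        for (int i = 0; i < ny; ++i) f[i] = g[base + i * nx];
        dt1d(f, ny, hy, d, v, z);
        for (int i = 0; i < ny; ++i) g[base + i * nx] = f[i];
      }
  // axis z
  if (nz > 1)
    for (int k2 = 0; k2 < ny; ++k2)
      for (int k1 = 0; k1 < nx; ++k1) {
        int base = k1 + k2 * nx;
        for (int i = 0; i < nz; ++i) f[i] = g[base + i * nx * ny];
        dt1d(f, nz, hz, d, v, z);
        for (int i = 0; i < nz; ++i) g[base + i * nx * ny] = f[i];
      }
  NumericVector out(g.begin(), g.end());
  out.attr("dim") = seed.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// Fast-marching reinitialization: rebuild a signed distance function from the
// zero-level set of phi, with sub-voxel initialization of the front so the
// interface does not move.
// ---------------------------------------------------------------------------

struct HeapNode {
  double d;
  int idx;
  bool operator>(const HeapNode &o) const { return d > o.d; }
};

// [[Rcpp::export(name = ".cpp_reinit")]]
NumericVector cpp_reinit(NumericVector phi, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
      nz = dims.size() > 2 ? dims[2] : 1;
  int n = nx * ny * nz;
  double h[3] = {spacing[0], spacing.size() > 1 ? spacing[1] : 1.0,
                 spacing.size() > 2 ? spacing[2] : 1.0};
  int stride[3] = {1, nx, nx * ny};
  int dim[3] = {nx, ny, nz};

  std::vector<double> dist(n, INF);
  std::vector<signed char> state(n, 0); // 0 far, 1 trial, 2 known
  std::vector<signed char> sgn(n);
  for (int i = 0; i < n; ++i) sgn[i] = (phi[i] >= 0) ? 1 : -1;

  // sub-voxel interface initialization
  bool any_cross = false;
  std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode> >
      heap;
  for (int k3 = 0; k3 < nz; ++k3)
    for (int k2 = 0; k2 < ny; ++k2)
      for (int k1 = 0; k1 < nx; ++k1) {
        int i = k1 + k2 * nx + k3 * nx * ny;
        int kk[3] = {k1, k2, k3};
        // per-axis sub-voxel crossing distances combined as a perpendicular
        // distance to a locally planar interface: 1/d^2 = sum_a 1/d_a^2
        double invsq = 0.0;
        bool cross = false;
        for (int a = 0; a < 3; ++a) {
          if (dim[a] == 1) continue;
          double da = INF;
          for (int dir = -1; dir <= 1; dir += 2) {
            int q = kk[a] + dir;
            if (q < 0 || q >= dim[a]) continue;
            int j = i + dir * stride[a];
            if (sgn[j] != sgn[i]) {
              double ap = std::fabs(phi[i]), aq = std::fabs(phi[j]);
              double denom = ap + aq;
              double frac = (denom > 1e-300) ? ap / denom : 0.0;
              da = std::min(da, h[a] * frac);
            }
          }
          if (da < INF) {
            cross = true;
            if (da < 1e-12) { invsq = INF; break; }
            invsq += 1.0 / (da * da);
          }
        }
        if (cross) {
          any_cross = true;
          dist[i] = (invsq == INF) ? 0.0 : 1.0 / std::sqrt(invsq);
          state[i] = 2;
        }
      }
  if (!any_cross) stop("level-set field has no zero crossing");

  // Eikonal update with second-order one-sided upwind differences where two
  // known points are available along an axis (first-order otherwise); the
  // quadratic is sum_a (alpha_a x - beta_a)^2 = 1.
  auto update = [&](int i, int k1, int k2, int k3) {
    int kk[3] = {k1, k2, k3};
    double al[3], be[3], m[3];
    int nm = 0;
    for (int a = 0; a < 3; ++a) {
      if (dim[a] == 1) continue;
      double best = INF;
      int bestdir = 0;
      for (int dir = -1; dir <= 1; dir += 2) {
        int q = kk[a] + dir;
        if (q < 0 || q >= dim[a]) continue;
        int j = i + dir * stride[a];
        if (state[j] == 2 && dist[j] < best) { best = dist[j]; bestdir = dir; }
      }
      if (best == INF) continue;
      double alpha = 1.0 / h[a], beta = best / h[a];
      int q2 = kk[a] + 2 * bestdir;
      if (q2 >= 0 && q2 < dim[a]) {
        int j2 = i + 2 * bestdir * stride[a];
        if (state[j2] == 2 && dist[j2] <= best) {
          alpha = 1.5 / h[a];
          beta = (2.0 * best - 0.5 * dist[j2]) / h[a];
        }
      }
      al[nm] = alpha; be[nm] = beta; m[nm] = best; ++nm;
    }
    if (nm == 0) return;
    // sort contributing axes by arrival value ascending
    for (int a = 1; a < nm; ++a)
      for (int b = a; b > 0 && m[b] < m[b - 1]; --b) {
        std::swap(m[b], m[b - 1]);
        std::swap(al[b], al[b - 1]);
        std::swap(be[b], be[b - 1]);
      }
    // try the largest consistent set of axes first; a solution is valid
    // when it exceeds every arrival value it uses
    double x = INF;
    for (int use = nm; use >= 1; --use) {
      double A = 0, B = 0, C = -1;
      for (int a = 0; a < use; ++a) {
        A += al[a] * al[a];
        B += -2.0 * al[a] * be[a];
        C += be[a] * be[a];
      }
      double disc = B * B - 4 * A * C;
      if (disc < 0) continue;
      double cand = (-B + std::sqrt(disc)) / (2 * A);
      if (cand >= m[use - 1]) { x = cand; break; }
    }
    if (x == INF) return;
    if (x < dist[i]) {
      dist[i] = x;
      state[i] = 1;
      heap.push(HeapNode{x, i});
    }
  };

  for (int k3 = 0; k3 < nz; ++k3)
    for (int k2 = 0; k2 < ny; ++k2)
      for (int k1 = 0; k1 < nx; ++k1) {
        int i = k1 + k2 * nx + k3 * nx * ny;
        if (state[i] != 2) update(i, k1, k2, k3);
      }

  while (!heap.empty()) {
    HeapNode nd = heap.top();
    heap.pop();
    int i = nd.idx;
    if (state[i] == 2) continue;
    state[i] = 2;
    dist[i] = nd.d;
    int k3 = i / (nx * ny), rem = i % (nx * ny);
    int k2 = rem / nx, k1 = rem % nx;
    int kk[3] = {k1, k2, k3};
    for (int a = 0; a < 3; ++a) {
      if (dim[a] == 1) continue;
      for (int dir = -1; dir <= 1; dir += 2) {
        int q = kk[a] + dir;
        if (q < 0 || q >= dim[a]) continue;
        int j = i + dir * stride[a];
        if (state[j] != 2) {
          int j3 = j / (nx * ny), jrem = j % (nx * ny);
          update(j, jrem % nx, jrem / nx, j3);
        }
      }
    }
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (dist[i] == INF ? 0.0 : dist[i]) * sgn[i];
  out.attr("dim") = phi.attr("dim");
  return out;
}
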