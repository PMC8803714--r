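// Low-level 3D image kernels: separable Gaussian blur, finite-difference
// Laplacian, ellipsoidal binary morphology, 26-connected components,
// scale-space local maxima, and a first-order upwind fast-marching solver.
// All arrays are column-major (R layout), dims = (nx, ny, nz).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// Separable Gaussian convolution; signal outside the grid is treated as 0,
// kernel truncated at 4 sigma and normalized (unit DC gain), so total
// activity is conserved for content away from the boundary.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> src(vol.begin(), vol.end()), dst(n);
  const int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma_vox[ax];
    if (s <= 1e-12) continue;
    int h = (int)std::ceil(4.0 * s);
    if (h < 1) h = 1;
    std::vector<double> k(2 * h + 1);
    double ks = 0.0;
    for (int i = -h; i <= h; ++i) {
      k[i + h] = std::exp(-0.5 * (double)i * i / (s * s));
      ks += k[i + h];
    }
    for (double &v : k) v /= ks;
    // keep the innermost loop contiguous (x) for cache efficiency
    if (ax == 0) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          const R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          for (int i = 0; i < nx; ++i) {
            double acc = 0.0;
            const int lo = std::max(0, i - h), hi = std::min(nx - 1, i + h);
            for (int j = lo; j <= hi; ++j)
              acc += k[j - i + h] * src[base + j];
            dst[base + i] = acc;
          }
        }
    } else if (ax == 1) {
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t zb = (R_xlen_t)nx * ny * z;
        for (int i = 0; i < ny; ++i) {
          double *out = &dst[zb + (R_xlen_t)nx * i];
          std::fill(out, out + nx, 0.0);
          const int lo = std::max(0, i - h), hi = std::min(ny - 1, i + h);
          for (int j = lo; j <= hi; ++j) {
            const double kv = k[j - i + h];
            const double *in = &src[zb + (R_xlen_t)nx * j];
            for (int x = 0; x < nx; ++x) out[x] += kv * in[x];
          }
        }
      }
    } else {
      const R_xlen_t plane = (R_xlen_t)nx * ny;
      for (int i = 0; i < nz; ++i) {
        double *out = &dst[plane * i];
        std::fill(out, out + plane, 0.0);
        const int lo = std::max(0, i - h), hi = std::min(nz - 1, i + h);
        for (int j = lo; j <= hi; ++j) {
          const double kv = k[j - i + h];
          const double *in = &src[plane * j];
          for (R_xlen_t p = 0; p < plane; ++p) out[p] += kv * in[p];
        }
      }
    }
    std::swap(src, dst);
  }
  return NumericVector(src.begin(), src.end());
}

// Second-order central-difference Laplacian in physical units (per mm^2);
// boundary faces are set to 0.
// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector vol, IntegerVector dim,
                            NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ihx2 = 1.0 / (spacing[0] * spacing[0]);
  const double ihy2 = 1.0 / (spacing[1] * spacing[1]);
  const double ihz2 = 1.0 / (spacing[2] * spacing[2]);
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 1; z < nz - 1; ++z)
    for (int y = 1; y < ny - 1; ++y)
      for (int x = 1; x < nx - 1; ++x) {
        const R_xlen_t i = idx3(x, y, z, nx, ny);
        const double c = vol[i];
        out[i] = (vol[i - 1] + vol[i + 1] - 2.0 * c) * ihx2 +
                 (vol[i - nx] + vol[i + nx] - 2.0 * c) * ihy2 +
                 (vol[i - (R_xlen_t)nx * ny] + vol[i + (R_xlen_t)nx * ny] -
                  2.0 * c) * ihz2;
      }
  return out;
}

// Ellipsoidal structuring element with per-axis radii in voxels
// (anisotropy-aware). erode = all offsets foreground (outside grid counts
// as background); dilate = any offset foreground.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        NumericVector rad_vox, bool erode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double rx = rad_vox[0], ry = rad_vox[1], rz = rad_vox[2];
  const int mx = (int)std::floor(rx + 1e-9);
  const int my = (int)std::floor(ry + 1e-9);
  const int mz = (int)std::floor(rz + 1e-9);
  std::vector<int> offs;
  for (int dz = -mz; dz <= mz; ++dz)
    for (int dy = -my; dy <= my; ++dy)
      for (int dx = -mx; dx <= mx; ++dx) {
        double d = 0.0;
        if (dx != 0) { if (rx <= 0) continue; d += (double)dx * dx / (rx * rx); }
        if (dy != 0) { if (ry <= 0) continue; d += (double)dy * dy / (ry * ry); }
        if (dz != 0) { if (rz <= 0) continue; d += (double)dz * dz / (rz * rz); }
        if (d <= 1.0 + 1e-9) {
          offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
        }
      }
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = idx3(x, y, z, nx, ny);
        if (erode && !mask[i]) { out[i] = FALSE; continue; }
        bool acc = erode;  // AND-identity for erode, OR-identity for dilate
        for (size_t o = 0; o < offs.size(); o += 3) {
          const int ux = x + offs[o], uy = y + offs[o + 1], uz = z + offs[o + 2];
          bool v = false;
          if (ux >= 0 && ux < nx && uy >= 0 && uy < ny && uz >= 0 && uz < nz)
            v = mask[idx3(ux, uy, uz, nx, ny)];
          if (erode) { if (!v) { acc = false; break; } }
          else       { if (v)  { acc = true;  break; } }
        }
        out[i] = acc;
      }
  return out;
}

// 26-connected component labelling, deterministic raster-scan BFS order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i0 = idx3(x, y, z, nx, ny);
        if (!mask[i0] || lab[i0] != 0) continue;
        ++next;
        lab[i0] = next;
        stack.push_back(i0);
        while (!stack.empty()) {
          const R_xlen_t i = stack.back();
          stack.pop_back();
          const int cz = (int)(i / ((R_xlen_t)nx * ny));
          const int cy = (int)((i / nx) % ny);
          const int cx = (int)(i % nx);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int ux = cx + dx, uy = cy + dy, uz = cz + dz;
                if (ux < 0 || ux >= nx || uy < 0 || uy >= ny ||
                    uz < 0 || uz >= nz) continue;
                const R_xlen_t u = idx3(ux, uy, uz, nx, ny);
                if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
              }
        }
      }
  return lab;
}

// Local maxima of a 4D scale-space response (nx, ny, nz, ns) over the
// 3x3x3x3 neighbourhood (80 neighbours), restricted to a 3D mask and a
// response threshold. Plateau ties are broken lexicographically (lowest
// linear 4D index wins) so results are deterministic.
// [[Rcpp::export]]
DataFrame cpp_scale_space_maxima(NumericVector resp, IntegerVector dim4,
                                 double threshold, LogicalVector mask) {
  const int nx = dim4[0], ny = dim4[1], nz = dim4[2], ns = dim4[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<int> vx, vy, vz, vs;
  std::vector<double> vv;
  for (int s = 0; s < ns; ++s)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t i3 = idx3(x, y, z, nx, ny);
          if (!mask[i3]) continue;
          const R_xlen_t i4 = i3 + (R_xlen_t)s * nvox;
          const double v = resp[i4];
          if (!(v >= threshold)) continue;
          bool is_max = true;
          for (int ds = -1; ds <= 1 && is_max; ++ds) {
            const int us = s + ds;
            if (us < 0 || us >= ns) continue;
            for (int dz = -1; dz <= 1 && is_max; ++dz)
              for (int dy = -1; dy <= 1 && is_max; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                  if (dx == 0 && dy == 0 && dz == 0 && ds == 0) continue;
                  const int ux = x + dx, uy = y + dy, uz = z + dz;
                  if (ux < 0 || ux >= nx || uy < 0 || uy >= ny ||
                      uz < 0 || uz >= nz) continue;
                  const R_xlen_t u4 =
                      idx3(ux, uy, uz, nx, ny) + (R_xlen_t)us * nvox;
                  const double nv = resp[u4];
                  if (nv > v || (nv == v && u4 < i4)) { is_max = false; break; }
                }
          }
          if (is_max) {
            vx.push_back(x); vy.push_back(y); vz.push_back(z);
            vs.push_back(s); vv.push_back(v);
          }
        }
  return DataFrame::create(_["x"] = vx, _["y"] = vy, _["z"] = vz,
                           _["s"] = vs, _["response"] = vv);
}

// First-order upwind fast marching on an anisotropic grid.
// Solves |grad T| = 1/F from a single seed voxel; propagation stops once
// arrival time exceeds t_max or Euclidean distance from the seed exceeds
// r_max. Heap ties are broken by linear voxel index for determinism.
// Returns arrival times (Inf where the front never arrived).
// [[Rcpp::export]]
NumericVector cpp_fast_march(NumericVector speed, IntegerVector dim,
                             NumericVector spacing, IntegerVector seed_vox,
                             double t_max, double r_max) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector T(n, INF);
  std::vector<unsigned char> state(n, 0);  // 0 far, 1 trial, 2 known
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;

  const int sx = seed_vox[0], sy = seed_vox[1], sz = seed_vox[2];
  const R_xlen_t si = idx3(sx, sy, sz, nx, ny);
  T[si] = 0.0;
  heap.push(Node(0.0, si));
  state[si] = 1;

  const int step[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  const double h_ax[3] = {hx, hy, hz};

  while (!heap.empty()) {
    const Node nd = heap.top();
    heap.pop();
    const R_xlen_t ci = nd.second;
    if (state[ci] == 2) continue;      // stale heap entry
    if (nd.first > t_max) break;       // monotone front: all later are larger
    state[ci] = 2;
    const int cz = (int)(ci / ((R_xlen_t)nx * ny));
    const int cy = (int)((ci / nx) % ny);
    const int cx = (int)(ci % nx);
    for (int d = 0; d < 6; ++d) {
      const int ux = cx + step[d][0], uy = cy + step[d][1], uz = cz + step[d][2];
      if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz)
        continue;
      const R_xlen_t ui = idx3(ux, uy, uz, nx, ny);
      if (state[ui] == 2) continue;
      const double ddx = (ux - sx) * hx, ddy = (uy - sy) * hy,
                   ddz = (uz - sz) * hz;
      if (ddx * ddx + ddy * ddy + ddz * ddz > r_max * r_max) continue;
      const double F = speed[ui];
      if (!(F > 0.0)) continue;
      // upwind neighbour values per axis
      double a[3];
      const int coords[3] = {ux, uy, uz};
      for (int ax = 0; ax < 3; ++ax) {
        double best = INF;
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int q[3] = {ux, uy, uz};
          q[ax] += sgn;
          if (q[ax] < 0 || q[ax] >= dim[ax]) continue;
          const R_xlen_t qi = idx3(q[0], q[1], q[2], nx, ny);
          if (state[qi] == 2 && T[qi] < best) best = T[qi];
        }
        a[ax] = best;
      }
      (void)coords;
      // solve sum_i ((t - a_i)/h_i)^2 = 1/F^2 over axes with a_i < t
      int ord[3] = {0, 1, 2};
      for (int i = 0; i < 2; ++i)
        for (int j = i + 1; j < 3; ++j)
          if (a[ord[j]] < a[ord[i]]) std::swap(ord[i], ord[j]);
      int nfin = 0;
      while (nfin < 3 && R_FINITE(a[ord[nfin]])) ++nfin;
      if (nfin == 0) continue;
      double tnew = INF;
      const double rhs = 1.0 / (F * F);
      // use the largest upwind stencil whose solution dominates its arrivals
      for (int m = nfin; m >= 1; --m) {
        double A = 0.0, B = 0.0, C = -rhs;
        for (int i = 0; i < m; ++i) {
          const double w = 1.0 / (h_ax[ord[i]] * h_ax[ord[i]]);
          A += w;
          B -= 2.0 * a[ord[i]] * w;
          C += a[ord[i]] * a[ord[i]] * w;
        }
        const double disc = B * B - 4.0 * A * C;
        if (disc < 0.0) continue;
        const double t = (-B + std::sqrt(disc)) / (2.0 * A);
        if (t >= a[ord[m - 1]]) { tnew = t; break; }
      }
      if (tnew < T[ui]) {
        T[ui] = tnew;
        state[ui] = 1;
        heap.push(Node(tnew, ui));
      }
    }
  }
  return T;
}
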