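// Grey-level matrix engines and geometry kernels for 3D radiomics.
// Level arrays are integer volumes in column-major order; 0 marks voxels
// outside the region of interest, in-region levels run 1..ng.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// the 13 unique 3D directions (half of the 26-neighbourhood)
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *m = &out[d * ng * ng];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          // symmetric accumulation
          m[(a - 1) + ng * (b - 1)] += 1.0;
          m[(b - 1) + ng * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxlen * 13);
  std::vector<char> seen(levels.size());
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *m = &out[d * ng * maxlen];
    std::fill(seen.begin(), seen.end(), 0);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x, y, z, nx, ny);
          if (seen[i]) continue;
          int a = levels[i];
          if (a == 0) { seen[i] = 1; continue; }
          // only start runs at voxels with no same-level predecessor
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[idx3(xp, yp, zp, nx, ny)] == a)
            continue;
          int len = 0, cx = x, cy = y, cz = z;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
            int j = idx3(cx, cy, cz, nx, ny);
            if (levels[j] != a) break;
            seen[j] = 1;
            ++len;
            cx += dx; cy += dy; cz += dz;
          }
          m[(a - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// zones of equal grey level under 26-connectivity; returns (level, size) pairs
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> visited(n, 0);
  std::vector<int> zlevel, zsize, stack;
  for (int start = 0; start < n; ++start) {
    if (visited[start] || levels[start] == 0) continue;
    int lev = levels[start], size = 0;
    stack.clear();
    stack.push_back(start);
    visited[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int j = idx3(x2, y2, z2, nx, ny);
            if (!visited[j] && levels[j] == lev) {
              visited[j] = 1;
              stack.push_back(j);
            }
          }
    }
    zlevel.push_back(lev);
    zsize.push_back(size);
  }
  IntegerMatrix out(zlevel.size(), 2);
  for (size_t i = 0; i < zlevel.size(); ++i) {
    out(i, 0) = zlevel[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// per-level neighbourhood grey-tone difference sums: columns n_i, s_i
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b == 0) continue;
              sum += b; ++cnt;
            }
        out(a - 1, 0) += 1.0;
        if (cnt > 0) out(a - 1, 1) += std::fabs((double)a - sum / cnt);
      }
  return out;
}

// dependence counts: matrix ng x 27, column j = dependence size j (1..27),
// dependence = 1 (centre) + neighbours within alpha of the centre level
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, IntegerVector dim, int ng,
                              double alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b == 0) continue;
              if (std::fabs((double)a - (double)b) <= alpha) ++dep;
            }
        out(a - 1, dep - 1) += 1.0;
      }
  return out;
}

// local first-order statistics on the (2r+1)^3 neighbourhood intersected with
// the mask: columns mean, variance, energy (mean square), entropy, uniformity.
// Entropy/uniformity use the discretized level volume.
// [[Rcpp::export]]
NumericMatrix cpp_local_stats(NumericVector image, IntegerVector levels,
                              IntegerVector dim, int r, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nvox = 0;
  for (int i = 0; i < levels.size(); ++i) if (levels[i] > 0) ++nvox;
  NumericMatrix out(nvox, 5);
  std::vector<double> hist(ng);
  int row = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i0 = idx3(x, y, z, nx, ny);
        if (levels[i0] == 0) continue;
        double s = 0.0, s2 = 0.0; int n = 0;
        std::fill(hist.begin(), hist.end(), 0.0);
        for (int dz = -r; dz <= r; ++dz)
          for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx) {
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int j = idx3(x2, y2, z2, nx, ny);
              if (levels[j] == 0) continue;
              double v = image[j];
              s += v; s2 += v * v; ++n;
              hist[levels[j] - 1] += 1.0;
            }
        if (n < 2) {
          // neighbourhood degenerates to the voxel itself
          double v = image[i0];
          out(row, 0) = v; out(row, 1) = 0.0; out(row, 2) = v * v;
          out(row, 3) = 0.0; out(row, 4) = 1.0;
        } else {
          double mean = s / n;
          out(row, 0) = mean;
          out(row, 1) = s2 / n - mean * mean;
          out(row, 2) = s2 / n;
          double ent = 0.0, unif = 0.0;
          for (int g = 0; g < ng; ++g) {
            if (hist[g] <= 0) continue;
            double p = hist[g] / n;
            ent -= p * std::log2(p);
            unif += p * p;
          }
          out(row, 3) = ent;
          out(row, 4) = unif;
        }
        ++row;
      }
  return out;
}

// Marching-tetrahedra iso-surface of {field == iso}. Surface area from the
// extracted triangles; volume by accumulating the clipped inside part of
// every tetrahedron (exact for the piecewise-linear interpolant). The field
// is assumed to fall below iso at the grid border so the surface is closed.
static inline void interp_pt(const double *p1, const double *p2, double v1,
                             double v2, double iso, double *q) {
  double t = (iso - v1) / (v2 - v1);
  q[0] = p1[0] + t * (p2[0] - p1[0]);
  q[1] = p1[1] + t * (p2[1] - p1[1]);
  q[2] = p1[2] + t * (p2[2] - p1[2]);
}

static inline double tri_area(const double *a, const double *b,
                              const double *c) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double n[3] = { u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2],
                  u[0]*v[1]-u[1]*v[0] };
  return 0.5 * std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
}

static inline double tet_vol(const double *a, const double *b,
                             const double *c, const double *d) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double w[3] = { d[0]-a[0], d[1]-a[1], d[2]-a[2] };
  double det = u[0]*(v[1]*w[2]-v[2]*w[1]) - u[1]*(v[0]*w[2]-v[2]*w[0]) +
               u[2]*(v[0]*w[1]-v[1]*w[0]);
  return std::fabs(det) / 6.0;
}

// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector field, IntegerVector dim,
                                   NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // Kuhn subdivision of the cube into 6 tetrahedra along diagonal 0-7
  // (corner ids bit-coded x|y<<1|z<<2)
  static const int TETS[6][4] = {
    {0,1,5,7},{0,5,4,7},{0,4,6,7},{0,6,2,7},{0,2,3,7},{0,3,1,7}
  };
  double area = 0.0, vol = 0.0;
  double P[8][3], V[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          V[c] = field[idx3(cx, cy, cz, nx, ny)];
          P[c][0] = cx * sx; P[c][1] = cy * sy; P[c][2] = cz * sz;
          if (V[c] > iso) any = true; else all = false;
        }
        if (all) { vol += sx * sy * sz; continue; }
        if (!any) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = TETS[t];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (V[tv[k]] > iso) ins[ni++] = tv[k]; else outs[no++] = tv[k];
          }
          if (ni == 0) continue;
          if (ni == 4) {
            vol += tet_vol(P[tv[0]], P[tv[1]], P[tv[2]], P[tv[3]]);
            continue;
          }
          if (ni == 1) {
            double q1[3], q2[3], q3[3];
            interp_pt(P[ins[0]], P[outs[0]], V[ins[0]], V[outs[0]], iso, q1);
            interp_pt(P[ins[0]], P[outs[1]], V[ins[0]], V[outs[1]], iso, q2);
            interp_pt(P[ins[0]], P[outs[2]], V[ins[0]], V[outs[2]], iso, q3);
            area += tri_area(q1, q2, q3);
            vol += tet_vol(P[ins[0]], q1, q2, q3);
          } else if (ni == 3) {
            double q1[3], q2[3], q3[3];
            interp_pt(P[ins[0]], P[outs[0]], V[ins[0]], V[outs[0]], iso, q1);
            interp_pt(P[ins[1]], P[outs[0]], V[ins[1]], V[outs[0]], iso, q2);
            interp_pt(P[ins[2]], P[outs[0]], V[ins[2]], V[outs[0]], iso, q3);
            area += tri_area(q1, q2, q3);
            vol += tet_vol(P[tv[0]], P[tv[1]], P[tv[2]], P[tv[3]]) -
                   tet_vol(P[outs[0]], q1, q2, q3);
          } else {  // ni == 2: quad cut; inside part is a wedge
            double qa[3], qb[3], qc[3], qd[3];
            interp_pt(P[ins[0]], P[outs[0]], V[ins[0]], V[outs[0]], iso, qa);
            interp_pt(P[ins[0]], P[outs[1]], V[ins[0]], V[outs[1]], iso, qb);
            interp_pt(P[ins[1]], P[outs[1]], V[ins[1]], V[outs[1]], iso, qc);
            interp_pt(P[ins[1]], P[outs[0]], V[ins[1]], V[outs[0]], iso, qd);
            area += tri_area(qa, qb, qc) + tri_area(qa, qc, qd);
            // convex fan from ins[0] over boundary faces not incident to it
            vol += tet_vol(P[ins[0]], P[ins[1]], qd, qc) +
                   tet_vol(P[ins[0]], qa, qb, qc) +
                   tet_vol(P[ins[0]], qa, qc, qd);
          }
        }
      }
  return NumericVector::create(area, vol);
}

// maximum pairwise Euclidean distance between rows of a point matrix
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = pts(i, k) - pts(j, k);
        s += diff * diff;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
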