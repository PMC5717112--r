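#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Reflected index: pads by mirroring about the edge voxel (..., 2, 1 | 2, ...).
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  if (i < 0) return -i;
  if (i >= n) return 2 * n - i - 2;
  return i;
}

// [[Rcpp::export(name = ".median_filter3_cpp")]]
NumericVector median_filter3_cpp(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  std::vector<double> win(27);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = refl(k + dk, nz);
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = refl(j + dj, ny);
            for (int di = -1; di <= 1; ++di) {
              const int ii = refl(i + di, nx);
              win[m++] = vol[ii + nx * (jj + (R_xlen_t)ny * kk)];
            }
          }
        }
        std::nth_element(win.begin(), win.begin() + 13, win.end());
        out[i + nx * (j + (R_xlen_t)ny * k)] = win[13];
      }
    }
  }
  return out;
}

// Quality-guided region-growing phase unwrap. Starting from the voxel of
// smallest |v|, voxels are merged in order of ascending wrapped difference
// to an already-unwrapped 6-neighbor; each new voxel is shifted by the
// multiple of 2*venc that matches that neighbor. Exact for wrap patterns
// over fields whose true neighbor differences stay below venc.
// [[Rcpp::export(name = ".unwrap_region_grow_cpp")]]
NumericVector unwrap_region_grow_cpp(NumericVector vol, IntegerVector dim,
                                     double venc) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(vol);
  std::vector<char> visited(n, 0);

  R_xlen_t seed = 0;
  double best = std::abs(out[0]);
  for (R_xlen_t i = 1; i < n; ++i) {
    const double a = std::abs(out[i]);
    if (a < best) { best = a; seed = i; }
  }

  struct Edge {
    double cost;
    R_xlen_t from, to;
    bool operator>(const Edge& o) const { return cost > o.cost; }
  };
  std::priority_queue<Edge, std::vector<Edge>, std::greater<Edge> > pq;

  const double period = 2.0 * venc;
  auto push_neighbors = [&](R_xlen_t i) {
    const int x = (int)(i % nx);
    const int y = (int)((i / nx) % ny);
    const int z = (int)(i / ((R_xlen_t)nx * ny));
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      const int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const R_xlen_t j = xx + nx * (yy + (R_xlen_t)ny * zz);
      if (visited[j]) continue;
      const double r = out[j] - out[i];
      const double wrapped = r - period * std::round(r / period);
      pq.push(Edge{std::abs(wrapped), i, j});
    }
  };

  visited[seed] = 1;
  push_neighbors(seed);
  while (!pq.empty()) {
    const Edge e = pq.top();
    pq.pop();
    if (visited[e.to]) continue;
    const double r = out[e.to] - out[e.from];
    out[e.to] -= period * std::round(r / period);
    visited[e.to] = 1;
    push_neighbors(e.to);
  }
  return out;
}
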