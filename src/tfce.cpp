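#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free cluster enhancement of a non-negative 3-D statistic map.
// enhanced(v) = sum over h = dh, 2dh, ... <= stat(v) of
//              size(component of v at threshold h)^E * h^H * dh
// Components are computed under 6/18/26-connectivity with an incremental
// union-find over voxels sorted by decreasing value.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector values, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) if (values[i] > vmax) vmax = values[i];
  if (vmax <= 0.0 || dh <= 0.0) return out;

  // neighbor offsets for the requested connectivity
  std::vector<int> odx, ody, odz;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
      }

  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (values[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  int nsteps = (int)std::floor(vmax / dh + 1e-12);
  size_t ptr = 0;
  std::vector<int> added;
  added.reserve(order.size());

  for (int k = nsteps; k >= 1; --k) {
    double h = k * dh;
    while (ptr < order.size() && values[order[ptr]] >= h) {
      int v = order[ptr++];
      active[v] = 1;
      csize[v] = 1;
      int x = v % nx, rest = v / nx;
      int y = rest % ny, z = rest / ny;
      for (size_t o = 0; o < odx.size(); ++o) {
        int xx = x + odx[o], yy = y + ody[o], zz = z + odz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int u = xx + nx * (yy + ny * zz);
        if (!active[u]) continue;
        int ru = find_root(parent, u), rv = find_root(parent, v);
        if (ru != rv) {
          if (csize[ru] < csize[rv]) std::swap(ru, rv);
          parent[rv] = ru;
          csize[ru] += csize[rv];
        }
      }
      added.push_back(v);
    }
    double hterm = std::pow(h, H) * dh;
    for (size_t a = 0; a < added.size(); ++a) {
      int v = added[a];
      out[v] += std::pow((double)csize[find_root(parent, v)], E) * hterm;
    }
  }
  return out;
}
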