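#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// 26-connected component labelling of a 3D logical mask stored in R's
// column-major order with dims (nz, ny, nx). Labels are assigned in
// scan order of the seed voxel (background = 0).
// [[Rcpp::export(name = ".label_cc3d")]]
IntegerVector label_cc3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              q.push(w);
            }
          }
        }
      }
    }
  }
  return labels;
}

// All unordered point pairs (i, j), i < j, with Euclidean distance
// <= radius, found with a uniform spatial hash of cell size = radius.
// coords is an n x 3 matrix (any consistent units). Returns a 2-column
// 1-based index matrix.
// [[Rcpp::export(name = ".pairs_within_radius")]]
IntegerMatrix pairs_within_radius(NumericMatrix coords, double radius) {
  const int n = coords.nrow();
  std::vector<int> ii, jj;
  if (n >= 2 && radius > 0) {
    double minc[3], maxc[3];
    for (int a = 0; a < 3; ++a) {
      minc[a] = maxc[a] = coords(0, a);
      for (int i = 1; i < n; ++i) {
        if (coords(i, a) < minc[a]) minc[a] = coords(i, a);
        if (coords(i, a) > maxc[a]) maxc[a] = coords(i, a);
      }
    }
    // injective packed cell key (cells are shifted to be non-negative)
    long long span[3];
    for (int a = 0; a < 3; ++a) {
      span[a] = (long long)std::floor((maxc[a] - minc[a]) / radius) + 3;
    }
    std::vector<long long> cell(3 * (size_t)n);
    std::unordered_map<long long, std::vector<int> > buckets;
    buckets.reserve((size_t)n * 2);
    const double r2 = radius * radius;
    for (int i = 0; i < n; ++i) {
      for (int a = 0; a < 3; ++a)
        cell[3 * (size_t)i + a] =
          (long long)std::floor((coords(i, a) - minc[a]) / radius);
      long long key =
        (cell[3 * (size_t)i] * span[1] + cell[3 * (size_t)i + 1]) *
          span[2] + cell[3 * (size_t)i + 2];
      buckets[key].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      long long cx = cell[3 * (size_t)i], cy = cell[3 * (size_t)i + 1],
                cz = cell[3 * (size_t)i + 2];
      for (long long ox = -1; ox <= 1; ++ox)
        for (long long oy = -1; oy <= 1; ++oy)
          for (long long oz = -1; oz <= 1; ++oz) {
            long long kx = cx + ox, ky = cy + oy, kz = cz + oz;
            if (kx < 0 || ky < 0 || kz < 0) continue;
            long long key = (kx * span[1] + ky) * span[2] + kz;
            std::unordered_map<long long,
                               std::vector<int> >::iterator it =
              buckets.find(key);
            if (it == buckets.end()) continue;
            const std::vector<int>& v = it->second;
            for (size_t k = 0; k < v.size(); ++k) {
              int j = v[k];
              if (j <= i) continue;
              double dx = coords(i, 0) - coords(j, 0);
              double dy = coords(i, 1) - coords(j, 1);
              double dz = coords(i, 2) - coords(j, 2);
              if (dx * dx + dy * dy + dz * dz <= r2) {
                ii.push_back(i + 1);
                jj.push_back(j + 1);
              }
            }
          }
    }
  }
  IntegerMatrix out((int)ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}
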