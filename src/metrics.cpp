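#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Label connected components of a 3D logical array.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns an integer vector (same length as mask) with 0 for background and
// component labels 1..K ordered by first raster occurrence, so label order is
// deterministic across platforms.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int order = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && order > 1) continue;
        if (connectivity == 18 && order > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }

  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)z * nx * ny);
      int y = rem / nx;
      int x = rem % nx;
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          q.push(w);
        }
      }
    }
  }
  return labels;
}

// For each point (row) of a, the Euclidean distance to the nearest point of b.
// Points are physical coordinates in mm (n x 3 matrices).
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  if (nb == 0) stop("reference point set is empty");
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nb; ++j) {
      double d0 = ax - b(j, 0), d1 = ay - b(j, 1), d2 = az - b(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
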