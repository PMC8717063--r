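#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stationary AR(1) recursion along rows. `innov` holds N(0, sd_innov) draws;
// column 0 is rescaled by 1/sqrt(1 - phi^2) so the process starts in its
// stationary distribution.
// [[Rcpp::export]]
NumericMatrix ar1_filter_cpp(NumericMatrix innov, double phi) {
  if (phi <= -1.0 || phi >= 1.0) stop("phi must lie in (-1, 1)");
  int v = innov.nrow(), t = innov.ncol();
  NumericMatrix out(v, t);
  double s0 = 1.0 / std::sqrt(1.0 - phi * phi);
  for (int i = 0; i < v; ++i) out(i, 0) = innov(i, 0) * s0;
  for (int j = 1; j < t; ++j)
    for (int i = 0; i < v; ++i)
      out(i, j) = phi * out(i, j - 1) + innov(i, j);
  return out;
}

// Row-wise Pearson correlation; NA for zero-variance rows.
// [[Rcpp::export]]
NumericVector row_pearson_cpp(NumericMatrix a, NumericMatrix b) {
  int v = a.nrow(), n = a.ncol();
  if (b.nrow() != v || b.ncol() != n) stop("dimension mismatch");
  NumericVector r(v);
  for (int i = 0; i < v; ++i) {
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (int j = 0; j < n; ++j) {
      double x = a(i, j), y = b(i, j);
      sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
    }
    double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
    if (vx <= 0 || vy <= 0) { r[i] = NA_REAL; continue; }
    r[i] = (sxy - sx * sy / n) / std::sqrt(vx * vy);
    if (r[i] > 1.0) r[i] = 1.0;
    if (r[i] < -1.0) r[i] = -1.0;
  }
  return r;
}

// Row-wise dot product (used on pre-standardised rows, where it equals the
// Pearson correlation). NaN rows propagate.
// [[Rcpp::export]]
NumericVector row_dot_cpp(NumericMatrix a, NumericMatrix b) {
  int v = a.nrow(), n = a.ncol();
  if (b.nrow() != v || b.ncol() != n) stop("dimension mismatch");
  NumericVector r(v);
  for (int i = 0; i < v; ++i) {
    double s = 0;
    for (int j = 0; j < n; ++j) s += a(i, j) * b(i, j);
    r[i] = s;
  }
  return r;
}

// Connected-component labeling of a 3D logical mask (vectorised in column-major
// order with dimensions `dim`). connectivity: 6 (faces) or 26 (faces+edges+
// corners). Labels are 1..K in order of first-encountered seed voxel; 0 = background.
// [[Rcpp::export]]
IntegerVector label_clusters_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((long long)nx * ny * nz != (long long)mask.size()) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  int n = mask.size();
  IntegerVector lab(n);
  std::vector<int> offx, offy, offz;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int nn = offx.size();
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (int k = 0; k < nn; ++k) {
        int x = cx + offx[k], y = cy + offy[k], z = cz + offz[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int idx = x + nx * (y + ny * z);
        if (mask[idx] && lab[idx] == 0) { lab[idx] = next; stack.push_back(idx); }
      }
    }
  }
  return lab;
}

// Size of the largest connected suprathreshold cluster — the permutation-null
// statistic. Avoids allocating a label map per permutation.
// [[Rcpp::export]]
int max_cluster_size_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  IntegerVector lab = label_clusters_cpp(mask, dim, connectivity);
  int n = lab.size(), k = 0;
  for (int i = 0; i < n; ++i) if (lab[i] > k) k = lab[i];
  if (k == 0) return 0;
  std::vector<int> cnt(k + 1, 0);
  for (int i = 0; i < n; ++i) if (lab[i] > 0) ++cnt[lab[i]];
  int m = 0;
  for (int c = 1; c <= k; ++c) if (cnt[c] > m) m = cnt[c];
  return m;
}
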