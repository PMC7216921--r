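#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Keep grid points whose distance to every atom is >= that atom's cutoff
// (strictly-inside points are removed). points: n x 3, atoms: m x 3.
// [[Rcpp::export]]
LogicalVector carve_keep_cpp(NumericMatrix points, NumericMatrix atoms,
                             NumericVector cutoff) {
  const int n = points.nrow(), m = atoms.nrow();
  if (cutoff.size() != m) stop("one cutoff per atom required");
  std::vector<double> c2(m);
  for (int j = 0; j < m; ++j) c2[j] = cutoff[j] * cutoff[j];
  LogicalVector keep(n, true);
  for (int i = 0; i < n; ++i) {
    const double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = x - atoms(j, 0), dy = y - atoms(j, 1),
                   dz = z - atoms(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2[j]) { keep[i] = false; break; }
    }
  }
  return keep;
}

// Squared distance from each point to its nearest atom.
// [[Rcpp::export]]
NumericVector min_sq_dist_cpp(NumericMatrix points, NumericMatrix atoms) {
  const int n = points.nrow(), m = atoms.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = x - atoms(j, 0), dy = y - atoms(j, 1),
                   dz = z - atoms(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = best;
  }
  return out;
}

// Enumerate supporting half-spaces of the convex hull of a 3-D point set by
// brute force over point triples: a plane through three points is a hull
// facet when all points lie on one side (within tol). Returns a k x 4
// matrix (a, b, c, d) with a*x + b*y + c*z + d <= tol for interior points.
// Intended for modest point counts (pocket-lining atom shells); cost is
// O(n^4) in the worst case.
// [[Rcpp::export]]
NumericMatrix hull_halfspaces_cpp(NumericMatrix pts, double tol = 1e-9) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3-D hull");
  std::vector<double> planes;
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 1; j < n - 1; ++j)
      for (int k = j + 1; k < n; ++k) {
        const double ux = pts(j, 0) - pts(i, 0), uy = pts(j, 1) - pts(i, 1),
                     uz = pts(j, 2) - pts(i, 2);
        const double vx = pts(k, 0) - pts(i, 0), vy = pts(k, 1) - pts(i, 1),
                     vz = pts(k, 2) - pts(i, 2);
        double a = uy * vz - uz * vy;
        double b = uz * vx - ux * vz;
        double c = ux * vy - uy * vx;
        const double norm = std::sqrt(a * a + b * b + c * c);
        if (norm < 1e-12) continue;  // collinear triple
        a /= norm; b /= norm; c /= norm;
        double d = -(a * pts(i, 0) + b * pts(i, 1) + c * pts(i, 2));
        bool pos = false, neg = false;
        for (int t = 0; t < n; ++t) {
          const double s = a * pts(t, 0) + b * pts(t, 1) + c * pts(t, 2) + d;
          if (s > tol) pos = true;
          else if (s < -tol) neg = true;
          if (pos && neg) break;
        }
        if (pos && neg) continue;  // not a supporting plane
        if (pos) { a = -a; b = -b; c = -c; d = -d; }  // orient inward (<= 0)
        planes.push_back(a); planes.push_back(b);
        planes.push_back(c); planes.push_back(d);
      }
  const int k = planes.size() / 4;
  if (k == 0) stop("degenerate point set: no supporting planes found");
  NumericMatrix out(k, 4);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = planes[4 * r + c];
  return out;
}

static inline std::int64_t cell_key(int i, int j, int k) {
  // pack three 21-bit signed lattice coordinates into one 64-bit key
  const std::int64_t B = 1 << 20;
  return ((std::int64_t)(i + B) << 42) | ((std::int64_t)(j + B) << 21) |
         (std::int64_t)(k + B);
}

// Connected components of lattice points under 26-neighbourhood adjacency.
// idx: n x 3 integer lattice coordinates. Returns 1-based component ids.
// [[Rcpp::export]]
IntegerVector lattice_components_cpp(IntegerMatrix idx) {
  const int n = idx.nrow();
  std::unordered_map<std::int64_t, int> where;
  where.reserve(2 * n);
  for (int i = 0; i < n; ++i)
    where[cell_key(idx(i, 0), idx(i, 1), idx(i, 2))] = i;
  IntegerVector comp(n, 0);
  int next_id = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (comp[s]) continue;
    ++next_id;
    stack.push_back(s);
    comp[s] = next_id;
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int ci = idx(cur, 0), cj = idx(cur, 1), ck = idx(cur, 2);
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          for (int dk = -1; dk <= 1; ++dk) {
            if (!di && !dj && !dk) continue;
            auto it = where.find(cell_key(ci + di, cj + dj, ck + dk));
            if (it != where.end() && !comp[it->second]) {
              comp[it->second] = next_id;
              stack.push_back(it->second);
            }
          }
    }
  }
  return comp;
}
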