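#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pair (squared distance, 0-based index) ordered lexicographically so that
// exact distance ties resolve to the lower point index. Queries are brute
// force: clouds here are a few 10^4 points, for which a linear scan with
// partial selection beats building a tree per call.
struct DistIdx {
  double d2;
  int idx;
  bool operator<(const DistIdx &o) const {
    if (d2 != o.d2) return d2 < o.d2;
    return idx < o.idx;
  }
};

static inline double sqdist3(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// k nearest neighbours (including the query point itself) of one point of the
// cloud, ordered by Euclidean distance on x,y,z, ties by ascending index.
// positions: n x 3; anchor: 1-based row index; returns 1-based indices.
// [[Rcpp::export(name = ".knnFromPoint")]]
IntegerVector knn_from_point(NumericMatrix positions, int anchor, int k) {
  const int n = positions.nrow();
  if (anchor < 1 || anchor > n) stop("anchor index out of range");
  if (k < 1) stop("k must be >= 1");
  const int m = std::min(k, n);

  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = positions(i, 0);
    py[i] = positions(i, 1);
    pz[i] = positions(i, 2);
  }
  const double ax = px[anchor - 1], ay = py[anchor - 1], az = pz[anchor - 1];

  std::vector<DistIdx> d(n);
  for (int i = 0; i < n; ++i) {
    double dx = px[i] - ax, dy = py[i] - ay, dz = pz[i] - az;
    d[i].d2 = dx * dx + dy * dy + dz * dz;
    d[i].idx = i;
  }
  std::partial_sort(d.begin(), d.begin() + m, d.end());

  IntegerVector out(m);
  for (int i = 0; i < m; ++i) out[i] = d[i].idx + 1;
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix, descending, via the trigonometric
// closed form (Smith 1961); robust for the small covariance matrices used in
// the shape descriptors.
static void eig_sym3(const double a[3][3], double ev[3]) {
  const double p1 = a[0][1] * a[0][1] + a[0][2] * a[0][2] + a[1][2] * a[1][2];
  const double tr = a[0][0] + a[1][1] + a[2][2];
  if (p1 == 0.0) {
    ev[0] = a[0][0]; ev[1] = a[1][1]; ev[2] = a[2][2];
    std::sort(ev, ev + 3, std::greater<double>());
    return;
  }
  const double q = tr / 3.0;
  const double p2 = (a[0][0] - q) * (a[0][0] - q) + (a[1][1] - q) * (a[1][1] - q) +
                    (a[2][2] - q) * (a[2][2] - q) + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  double b[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) b[i][j] = (a[i][j] - (i == j ? q : 0.0)) / p;
  double detb = b[0][0] * (b[1][1] * b[2][2] - b[1][2] * b[2][1]) -
                b[0][1] * (b[1][0] * b[2][2] - b[1][2] * b[2][0]) +
                b[0][2] * (b[1][0] * b[2][1] - b[1][1] * b[2][0]);
  double r = detb / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  const double phi = std::acos(r) / 3.0;
  ev[0] = q + 2.0 * p * std::cos(phi);
  ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  ev[1] = tr - ev[0] - ev[2];
}

// Per-point covariance shape descriptors (linearity, planarity, sphericity)
// from the kLocal nearest neighbours of each point *within* the given set of
// positions (a chunk view). Brute force: chunks are O(10^2..10^4) points.
// [[Rcpp::export(name = ".localShapeFeatures")]]
NumericMatrix local_shape_features(NumericMatrix positions, int kLocal) {
  const int n = positions.nrow();
  const int m = std::min(kLocal, n);
  NumericMatrix out(n, 3);

  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = positions(i, 0);
    pts[3 * i + 1] = positions(i, 1);
    pts[3 * i + 2] = positions(i, 2);
  }

  std::vector<DistIdx> d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      d[j].d2 = sqdist3(&pts[3 * i], &pts[3 * j]);
      d[j].idx = j;
    }
    std::partial_sort(d.begin(), d.begin() + m, d.end());

    double mean[3] = {0, 0, 0};
    for (int j = 0; j < m; ++j)
      for (int c = 0; c < 3; ++c) mean[c] += pts[3 * d[j].idx + c];
    for (int c = 0; c < 3; ++c) mean[c] /= m;

    double cov[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = 0; j < m; ++j) {
      double v[3];
      for (int c = 0; c < 3; ++c) v[c] = pts[3 * d[j].idx + c] - mean[c];
      for (int r = 0; r < 3; ++r)
        for (int c = r; c < 3; ++c) cov[r][c] += v[r] * v[c];
    }
    for (int r = 0; r < 3; ++r)
      for (int c = r; c < 3; ++c) {
        cov[r][c] /= m;
        cov[c][r] = cov[r][c];
      }

    double ev[3];
    eig_sym3(cov, ev);
    for (int c = 0; c < 3; ++c) ev[c] = std::max(ev[c], 0.0);
    const double l1 = ev[0];
    if (l1 <= 0.0) {
      out(i, 0) = 0.0; out(i, 1) = 0.0; out(i, 2) = 0.0;
    } else {
      out(i, 0) = (ev[0] - ev[1]) / l1;  // linearity
      out(i, 1) = (ev[1] - ev[2]) / l1;  // planarity
      out(i, 2) = ev[2] / l1;            // sphericity
    }
  }
  return out;
}
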