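#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in mutual information in bits between two integer-coded vectors.
// Codes are small integers (ternary -1/0/1, CNV -2..2, labels +/-1);
// contingency cells with zero counts contribute nothing (0*log 0 = 0).
static double mi_counts(const int* x, const int* y, int n,
                        int xmin, int xmax, int ymin, int ymax) {
  const int nx = xmax - xmin + 1, ny = ymax - ymin + 1;
  std::vector<int> joint(nx * ny, 0), mx(nx, 0), my(ny, 0);
  for (int i = 0; i < n; ++i) {
    const int a = x[i] - xmin, b = y[i] - ymin;
    joint[a * ny + b]++;
    mx[a]++;
    my[b]++;
  }
  const double dn = static_cast<double>(n);
  double mi = 0.0;
  for (int a = 0; a < nx; ++a) {
    if (mx[a] == 0) continue;
    for (int b = 0; b < ny; ++b) {
      const int c = joint[a * ny + b];
      if (c == 0) continue;
      const double pab = c / dn;
      mi += pab * std::log2(c * dn / (static_cast<double>(mx[a]) * my[b]));
    }
  }
  return mi > 0.0 ? mi : 0.0;
}

static void int_range(const int* x, int n, int& lo, int& hi) {
  lo = hi = x[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < lo) lo = x[i];
    if (x[i] > hi) hi = x[i];
  }
  if (hi - lo > 10000) stop("categorical codes span too wide a range");
}

// [[Rcpp::export]]
double mi_discrete_cpp(IntegerVector x, IntegerVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  if (n < 1) stop("need at least one observation");
  int xlo, xhi, ylo, yhi;
  int_range(x.begin(), n, xlo, xhi);
  int_range(y.begin(), n, ylo, yhi);
  return mi_counts(x.begin(), y.begin(), n, xlo, xhi, ylo, yhi);
}

// [[Rcpp::export]]
NumericVector relevance_cpp(IntegerMatrix X, IntegerVector y) {
  const int n = X.nrow(), p = X.ncol();
  if (n != y.size()) stop("label length must match row count");
  int ylo, yhi;
  int_range(y.begin(), n, ylo, yhi);
  NumericVector rel(p);
  for (int j = 0; j < p; ++j) {
    const int* xj = &X(0, j);
    int lo, hi;
    int_range(xj, n, lo, hi);
    rel[j] = mi_counts(xj, y.begin(), n, lo, hi, ylo, yhi);
  }
  return rel;
}

// Incremental mRMR ranking: step m selects the unpicked feature maximizing
// relevance minus mean mutual information with the already-selected set.
// Ties: higher relevance, then lower column index. Pairwise MI is computed
// only against selected features (cached as a running sum), never the full
// pairwise matrix.
// [[Rcpp::export]]
List mrmr_rank_cpp(IntegerMatrix X, IntegerVector y, int cap) {
  const int n = X.nrow(), p = X.ncol();
  if (n != y.size()) stop("label length must match row count");
  if (p < 1) stop("need at least one feature");
  const int k = std::min(cap, p);

  NumericVector rel = relevance_cpp(X, y);
  std::vector<int> clo(p), chi(p);
  for (int j = 0; j < p; ++j) int_range(&X(0, j), n, clo[j], chi[j]);

  std::vector<bool> picked(p, false);
  std::vector<double> redsum(p, 0.0);
  IntegerVector order(k);
  NumericVector score(k);

  // first pick: pure max relevance
  int best = 0;
  for (int j = 1; j < p; ++j)
    if (rel[j] > rel[best]) best = j;
  order[0] = best + 1;
  score[0] = rel[best];
  picked[best] = true;
  int last = best;

  for (int m = 1; m < k; ++m) {
    const double inv = 1.0 / m;
    int bj = -1;
    double bcrit = 0.0, brel = 0.0;
    for (int j = 0; j < p; ++j) {
      if (picked[j]) continue;
      redsum[j] += mi_counts(&X(0, j), &X(0, last), n,
                             clo[j], chi[j], clo[last], chi[last]);
      const double crit = rel[j] - inv * redsum[j];
      if (bj < 0 || crit > bcrit ||
          (crit == bcrit && (rel[j] > brel ||
                             (rel[j] == brel && j < bj)))) {
        bj = j;
        bcrit = crit;
        brel = rel[j];
      }
    }
    order[m] = bj + 1;
    score[m] = bcrit;
    picked[bj] = true;
    last = bj;
  }
  return List::create(_["order"] = order, _["score"] = score,
                      _["relevance"] = rel);
}

// SMO solver for the C-SVC dual with a precomputed kernel:
//   min_a  0.5 a' Q a - sum(a)   s.t. 0 <= a_i <= C, sum(a_i y_i) = 0,
// Q_ij = y_i y_j K_ij. Maximal-violating-pair working set selection.
// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, IntegerVector y, double C, double eps,
                   int max_iter, NumericVector alpha0) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length must match kernel size");

  std::vector<double> a(n), G(n);
  const bool warm = alpha0.size() == n;
  for (int i = 0; i < n; ++i) a[i] = warm ? alpha0[i] : 0.0;

  // gradient G_i = (Q a)_i - 1
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    if (warm) {
      for (int j = 0; j < n; ++j)
        if (a[j] > 0.0) s += a[j] * y[i] * y[j] * K(j, i);
    }
    G[i] = s - 1.0;
  }

  int iter = 0;
  double gap = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    // i: argmax F over I_up, j: argmin F over I_low, F_t = -y_t G_t
    int wi = -1, wj = -1;
    double Fmax = -R_PosInf, Fmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double F = -y[t] * G[t];
      const bool up = (y[t] == 1 && a[t] < C) || (y[t] == -1 && a[t] > 0.0);
      const bool low = (y[t] == 1 && a[t] > 0.0) || (y[t] == -1 && a[t] < C);
      if (up && F > Fmax) { Fmax = F; wi = t; }
      if (low && F < Fmin) { Fmin = F; wj = t; }
    }
    gap = Fmax - Fmin;
    if (wi < 0 || wj < 0 || gap <= eps) break;

    double eta = K(wi, wi) + K(wj, wj) - 2.0 * K(wi, wj);
    if (eta <= 1e-12) eta = 1e-12;
    double t = gap / eta;

    // feasible step bound keeping both multipliers inside [0, C]
    double tmax = (y[wi] == 1) ? (C - a[wi]) : a[wi];
    const double tmax2 = (y[wj] == 1) ? a[wj] : (C - a[wj]);
    if (tmax2 < tmax) tmax = tmax2;
    if (t > tmax) t = tmax;
    if (t <= 0.0) break;

    const double dai = y[wi] * t, daj = -y[wj] * t;
    a[wi] += dai;
    a[wj] += daj;
    for (int u = 0; u < n; ++u)
      G[u] += y[u] * y[wi] * K(wi, u) * dai + y[u] * y[wj] * K(wj, u) * daj;
  }

  // bias from KKT: b = -y_i G_i averaged over free support vectors
  double bsum = 0.0;
  int bcnt = 0;
  const double tolC = 1e-10 * std::max(1.0, C);
  for (int i = 0; i < n; ++i) {
    if (a[i] > tolC && a[i] < C - tolC) {
      bsum += -y[i] * G[i];
      bcnt++;
    }
  }
  double b;
  if (bcnt > 0) {
    b = bsum / bcnt;
  } else {
    double Fmax = -R_PosInf, Fmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double F = -y[t] * G[t];
      const bool up = (y[t] == 1 && a[t] < C) || (y[t] == -1 && a[t] > 0.0);
      const bool low = (y[t] == 1 && a[t] > 0.0) || (y[t] == -1 && a[t] < C);
      if (up && F > Fmax) Fmax = F;
      if (low && F < Fmin) Fmin = F;
    }
    b = (Fmax + Fmin) / 2.0;
  }

  // dual objective sum(a) - 0.5 a'Qa = sum(a) - 0.5 sum_i a_i (G_i + 1)
  double obj = 0.0;
  for (int i = 0; i < n; ++i) obj += a[i] - 0.5 * a[i] * (G[i] + 1.0);

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["iterations"] = iter, _["kkt_gap"] = gap,
                      _["converged"] = (gap <= eps));
}
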