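#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Deterministic SMO solver for the soft-margin C-SVC dual with a linear
// kernel (maximal-violating-pair working-set selection, no shrinking).
// Problem sizes here are tiny (tens of training trials), so a dense Gram
// matrix and exhaustive pair selection are both exact and fast.
namespace {

struct SvcModel {
  std::vector<double> alpha;
  double rho;
  int iter;
};

// K: n x n Gram matrix (row-major contiguous), y in {-1,+1}
SvcModel smo_solve(const std::vector<double> &K, const std::vector<int> &y,
                   int n, double C, double tol, int max_iter) {
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  while (iter < max_iter) {
    // working set: maximal violating pair
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0.0);
      bool low = (y[t] == 1) ? (alpha[t] > 0.0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
           Kij = K[(size_t)i * n + j];
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      // curvature along the feasible direction is ||x_i - x_j||^2
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t) {
        G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * dai +
                        y[j] * K[(size_t)j * n + t] * daj);
      }
    }
    ++iter;
  }

  // rho from KKT conditions (mean over free SVs, else midpoint of bounds)
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double free_sum = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0.0) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      free_sum += yG;
      ++nfree;
    }
  }
  double rho = (nfree > 0) ? free_sum / nfree : (ub + lb) / 2.0;
  SvcModel m;
  m.alpha = alpha;
  m.rho = rho;
  m.iter = iter;
  return m;
}

void gram(const NumericMatrix &X, const std::vector<int> &rows,
          std::vector<double> &K) {
  int n = (int)rows.size(), p = X.ncol();
  K.assign((size_t)n * n, 0.0);
  for (int a = 0; a < n; ++a) {
    for (int b = a; b < n; ++b) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) s += X(rows[a], c) * X(rows[b], c);
      K[(size_t)a * n + b] = s;
      K[(size_t)b * n + a] = s;
    }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".linear_svc_fit_cpp")]]
List linear_svc_fit_cpp(NumericMatrix X, IntegerVector y, double C,
                        double tol = 1e-8, int max_iter = 1000000) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("label length mismatch");
  std::vector<int> yy(n);
  for (int t = 0; t < n; ++t) {
    if (y[t] != 1 && y[t] != -1) stop("labels must be +1/-1");
    yy[t] = y[t];
  }
  std::vector<int> rows(n);
  for (int t = 0; t < n; ++t) rows[t] = t;
  std::vector<double> K;
  gram(X, rows, K);
  SvcModel m = smo_solve(K, yy, n, C, tol, max_iter);

  NumericVector w(p);
  for (int t = 0; t < n; ++t) {
    double c = m.alpha[t] * yy[t];
    if (c != 0.0)
      for (int c2 = 0; c2 < p; ++c2) w[c2] += c * X(t, c2);
  }
  return List::create(_["w"] = w, _["rho"] = m.rho,
                      _["alpha"] = NumericVector(m.alpha.begin(), m.alpha.end()),
                      _["iterations"] = m.iter);
}

// Fold-wise fit/predict over many label columns sharing one feature matrix.
// X: all selected trials x features; Y: n x m matrix of +/-1 labels (one
// column per permutation); train/test: lists of 1-based row index vectors.
// Returns fold-fraction-correct matrix (n_folds x m). Ties |dv| <= dv_tol
// are assigned to tie_class.
//' @noRd
// [[Rcpp::export(name = ".fold_accuracy_cpp")]]
NumericMatrix fold_accuracy_cpp(NumericMatrix X, IntegerMatrix Y,
                                List train, List test, double C,
                                int tie_class, double dv_tol = 1e-12,
                                double tol = 1e-8, int max_iter = 1000000) {
  int m = Y.ncol();
  int nf = train.size();
  if (test.size() != nf) stop("fold list mismatch");
  int p = X.ncol();
  NumericMatrix out(nf, m);

  for (int f = 0; f < nf; ++f) {
    IntegerVector tr = train[f], te = test[f];
    int ntr = tr.size(), nte = te.size();
    std::vector<int> rows(ntr), terows(nte);
    for (int a = 0; a < ntr; ++a) rows[a] = tr[a] - 1;
    for (int a = 0; a < nte; ++a) terows[a] = te[a] - 1;
    std::vector<double> K;
    gram(X, rows, K);
    // cross kernel test x train
    std::vector<double> Kc((size_t)nte * ntr);
    for (int a = 0; a < nte; ++a)
      for (int b = 0; b < ntr; ++b) {
        double s = 0.0;
        for (int c = 0; c < p; ++c) s += X(terows[a], c) * X(rows[b], c);
        Kc[(size_t)a * ntr + b] = s;
      }
    std::vector<int> yy(ntr), yte(nte);
    for (int col = 0; col < m; ++col) {
      for (int a = 0; a < ntr; ++a) yy[a] = Y(rows[a], col);
      for (int a = 0; a < nte; ++a) yte[a] = Y(terows[a], col);
      SvcModel mod = smo_solve(K, yy, ntr, C, tol, max_iter);
      int correct = 0;
      for (int a = 0; a < nte; ++a) {
        double dv = -mod.rho;
        for (int b = 0; b < ntr; ++b) {
          double c2 = mod.alpha[b] * yy[b];
          if (c2 != 0.0) dv += c2 * Kc[(size_t)a * ntr + b];
        }
        int pred;
        if (dv > dv_tol) pred = 1;
        else if (dv < -dv_tol) pred = -1;
        else pred = tie_class;
        if (pred == yte[a]) ++correct;
      }
      out(f, col) = nte > 0 ? (double)correct / nte : NA_REAL;
    }
  }
  return out;
}
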