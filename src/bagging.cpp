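#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Feature-bagging engine. Each bag is a uniform draw of `bag_size` distinct
// feature columns; the two groups are classified from those columns with
// cross-validation and the accuracy recorded. Bags are drawn with R's RNG so
// results are reproducible from set.seed() on the R side.
//
// Classifier codes:
//   0 ridge      L2-regularised least-squares discriminant; exact LOO via the
//                PRESS identity (one factorisation per bag), refit per fold
//                under k-fold CV.
//   1 centroid   nearest class-centroid (Gaussian, shared isotropic scale).
//   2 stump      mean-split decision stump per bag feature, majority vote.
//   3 svm        max-margin linear (squared-hinge loss), Newton solver,
//                refit per fold. Slow; intended for cross-checks.

static const double CHOL_TOL = 1e-12;

// Cholesky of SPD A (m x m, row-major, full storage) into lower-tri L.
static bool chol_factor(const double* A, double* L, int m) {
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * m + j];
      for (int k = 0; k < j; ++k) s -= L[i * m + k] * L[j * m + k];
      if (i == j) {
        if (s < CHOL_TOL) return false;
        L[i * m + i] = std::sqrt(s);
      } else {
        L[i * m + j] = s / L[j * m + j];
      }
    }
  }
  return true;
}

static void forward_solve(const double* L, const double* b, double* u, int m) {
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * m + k] * u[k];
    u[i] = s / L[i * m + i];
  }
}

static void back_solve(const double* L, const double* u, double* x, int m) {
  for (int i = m - 1; i >= 0; --i) {
    double s = u[i];
    for (int k = i + 1; k < m; ++k) s -= L[k * m + i] * x[k];
    x[i] = s / L[i * m + i];
  }
}

// Exact leave-one-out for ridge via PRESS: loo_pred_i = (yhat_i - h_i y_i)/(1 - h_i).
// Z: n x m column-major with intercept as column 0. The bag's normal
// equations are gathered from a precomputed (triangularly packed) feature
// Gram matrix; leverages use the explicit inverse A = G^-1, which avoids
// per-subject triangular solves.
static double ridge_loo_accuracy(const double* Z, const int* y, int n, int m,
                                 double lambda, const double* gram_lt,
                                 const size_t* rowoff, const double* colsum,
                                 const double* xty, double ysum,
                                 const int* bag, double* G, double* L,
                                 double* beta, double* work) {
  const int q = m - 1;
  G[0] = n + lambda;
  for (int a = 0; a < q; ++a) {
    const int ja = bag[a];
    G[(a + 1) * m] = colsum[ja];
    G[a + 1] = colsum[ja];
    for (int b = 0; b <= a; ++b) {
      const int jb = bag[b];
      double s = (ja >= jb) ? gram_lt[rowoff[ja] + jb]
                            : gram_lt[rowoff[jb] + ja];
      G[(a + 1) * m + (b + 1)] = s;
      G[(b + 1) * m + (a + 1)] = s;
    }
    G[(a + 1) * m + (a + 1)] += lambda;
  }
  if (!chol_factor(G, L, m)) return NA_REAL;
  double* c = work;                // m
  double* u = work + m;            // m
  double* zi = work + 2 * m;       // m
  double* Linv = work + 3 * m;     // m*m (lower)
  double* A = Linv + m * m;        // m*m symmetric inverse
  c[0] = ysum;
  for (int a = 0; a < q; ++a) c[a + 1] = xty[bag[a]];
  forward_solve(L, c, u, m);
  back_solve(L, u, beta, m);
  // invert L (lower triangular), then A = Linv' Linv
  for (int j = 0; j < m; ++j) {
    double dj = 1.0 / L[j * m + j];
    Linv[j * m + j] = dj;
    for (int i = j + 1; i < m; ++i) {
      double s = 0.0;
      for (int k = j; k < i; ++k) s += L[i * m + k] * Linv[k * m + j];
      Linv[i * m + j] = -s / L[i * m + i];
    }
  }
  for (int a = 0; a < m; ++a) {
    for (int b = 0; b <= a; ++b) {
      double s = 0.0;
      for (int k = a; k < m; ++k) s += Linv[k * m + a] * Linv[k * m + b];
      A[a * m + b] = s;
      A[b * m + a] = s;
    }
  }
  int correct = 0;
  for (int i = 0; i < n; ++i) {
    double yhat = beta[0];
    zi[0] = 1.0;
    for (int a = 1; a < m; ++a) {
      zi[a] = Z[(size_t)a * n + i];
      yhat += zi[a] * beta[a];
    }
    double h = 0.0;
    for (int a = 0; a < m; ++a) {
      const double* Aa = A + a * m;
      double s = 0.0;
      for (int b = 0; b < m; ++b) s += Aa[b] * zi[b];
      h += s * zi[a];
    }
    if (h > 1.0 - 1e-10) h = 1.0 - 1e-10;
    double pred = (yhat - h * y[i]) / (1.0 - h);
    if ((pred >= 0.0) == (y[i] > 0)) ++correct;
  }
  return (double)correct / n;
}

// Ridge with explicit folds: downdate full G and c by the held-out rows.
static double ridge_kfold_accuracy(const double* Z, const int* y, int n, int m,
                                   double lambda, const int* foldid, int K,
                                   double* G0, double* G, double* L,
                                   double* beta, double* work) {
  for (int a = 0; a < m; ++a) {
    const double* za = Z + (size_t)a * n;
    for (int b = 0; b <= a; ++b) {
      const double* zb = Z + (size_t)b * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += za[i] * zb[i];
      G0[a * m + b] = s;
      G0[b * m + a] = s;
    }
  }
  double* c0 = work;          // m
  double* c = work + m;       // m
  double* u = work + 2 * m;   // m
  double* zi = work + 3 * m;  // m
  for (int a = 0; a < m; ++a) {
    const double* za = Z + (size_t)a * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += za[i] * y[i];
    c0[a] = s;
  }
  int correct = 0, total = 0;
  for (int f = 0; f < K; ++f) {
    std::memcpy(G, G0, sizeof(double) * m * m);
    std::memcpy(c, c0, sizeof(double) * m);
    int nfold = 0;
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != f) continue;
      ++nfold;
      for (int a = 0; a < m; ++a) zi[a] = Z[(size_t)a * n + i];
      for (int a = 0; a < m; ++a) {
        for (int b = 0; b < m; ++b) G[a * m + b] -= zi[a] * zi[b];
        c[a] -= zi[a] * y[i];
      }
    }
    if (nfold == 0) continue;
    for (int a = 0; a < m; ++a) G[a * m + a] += lambda;
    if (!chol_factor(G, L, m)) return NA_REAL;
    forward_solve(L, c, u, m);
    back_solve(L, u, beta, m);
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != f) continue;
      double pred = 0.0;
      for (int a = 0; a < m; ++a) pred += Z[(size_t)a * n + i] * beta[a];
      if ((pred >= 0.0) == (y[i] > 0)) ++correct;
      ++total;
    }
  }
  return (double)correct / total;
}

// Nearest class-centroid with fold-wise downdating of the class sums.
// Feature columns of Z start at column 1 (column 0 is the intercept, unused).
static double centroid_accuracy(const double* Z, const int* y, int n, int m,
                                const int* foldid, int K, double* sump,
                                double* sumc) {
  int q = m - 1;
  int np = 0, nc = 0;
  for (int a = 0; a < q; ++a) { sump[a] = 0.0; sumc[a] = 0.0; }
  for (int i = 0; i < n; ++i) {
    if (y[i] > 0) ++np; else ++nc;
    for (int a = 0; a < q; ++a) {
      double v = Z[(size_t)(a + 1) * n + i];
      if (y[i] > 0) sump[a] += v; else sumc[a] += v;
    }
  }
  int correct = 0, total = 0;
  std::vector<double> mp(q), mc(q);
  for (int f = 0; f < K; ++f) {
    double sp, sc;
    int npf = np, ncf = nc;
    std::vector<double> dp(q, 0.0), dc(q, 0.0);
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != f) continue;
      if (y[i] > 0) --npf; else --ncf;
      for (int a = 0; a < q; ++a) {
        double v = Z[(size_t)(a + 1) * n + i];
        if (y[i] > 0) dp[a] += v; else dc[a] += v;
      }
    }
    if (npf < 1 || ncf < 1) {
      // degenerate training fold: predict the training majority class
      int maj = (npf >= ncf) ? 1 : -1;
      for (int i = 0; i < n; ++i)
        if (foldid[i] == f) { if (y[i] == maj) ++correct; ++total; }
      continue;
    }
    for (int a = 0; a < q; ++a) {
      mp[a] = (sump[a] - dp[a]) / npf;
      mc[a] = (sumc[a] - dc[a]) / ncf;
    }
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != f) continue;
      sp = 0.0; sc = 0.0;
      for (int a = 0; a < q; ++a) {
        double v = Z[(size_t)(a + 1) * n + i];
        sp += (v - mp[a]) * (v - mp[a]);
        sc += (v - mc[a]) * (v - mc[a]);
      }
      int pred = (sp <= sc) ? 1 : -1;
      if (pred == y[i]) ++correct;
      ++total;
    }
  }
  return (double)correct / total;
}

// Mean-split decision stump per feature, majority vote over the bag.
static double stump_accuracy(const double* Z, const int* y, int n, int m,
                             const int* foldid, int K, double* sump,
                             double* sumc) {
  int q = m - 1;
  int np = 0, nc = 0;
  for (int a = 0; a < q; ++a) { sump[a] = 0.0; sumc[a] = 0.0; }
  for (int i = 0; i < n; ++i) {
    if (y[i] > 0) ++np; else ++nc;
    for (int a = 0; a < q; ++a) {
      double v = Z[(size_t)(a + 1) * n + i];
      if (y[i] > 0) sump[a] += v; else sumc[a] += v;
    }
  }
  int correct = 0, total = 0;
  std::vector<double> thr(q), ori(q);
  for (int f = 0; f < K; ++f) {
    int npf = np, ncf = nc;
    std::vector<double> dp(q, 0.0), dc(q, 0.0);
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != f) continue;
      if (y[i] > 0) --npf; else --ncf;
      for (int a = 0; a < q; ++a) {
        double v = Z[(size_t)(a + 1) * n + i];
        if (y[i] > 0) dp[a] += v; else dc[a] += v;
      }
    }
    if (npf < 1 || ncf < 1) {
      int maj = (npf >= ncf) ? 1 : -1;
      for (int i = 0; i < n; ++i)
        if (foldid[i] == f) { if (y[i] == maj) ++correct; ++total; }
      continue;
    }
    for (int a = 0; a < q; ++a) {
      double mp = (sump[a] - dp[a]) / npf;
      double mc = (sumc[a] - dc[a]) / ncf;
      thr[a] = 0.5 * (mp + mc);
      ori[a] = (mp >= mc) ? 1.0 : -1.0;
    }
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != f) continue;
      double vote = 0.0;
      for (int a = 0; a < q; ++a) {
        double v = Z[(size_t)(a + 1) * n + i];
        vote += ori[a] * ((v >= thr[a]) ? 1.0 : -1.0);
      }
      int pred = (vote >= 0.0) ? 1 : -1;
      if (pred == y[i]) ++correct;
      ++total;
    }
  }
  return (double)correct / total;
}

// Squared-hinge max-margin linear classifier, Newton iterations, refit per fold.
static double svm_accuracy(const double* Z, const int* y, int n, int m,
                           double lambda, const int* foldid, int K, double* G,
                           double* L, double* w, double* work) {
  double* grad = work;
  double* d = work + m;
  double* u = work + 2 * m;
  double* fi = work + 3 * m;  // n
  int correct = 0, total = 0;
  for (int f = 0; f < K; ++f) {
    for (int a = 0; a < m; ++a) w[a] = 0.0;
    for (int iter = 0; iter < 50; ++iter) {
      // residuals and active set on training rows
      for (int a = 0; a < m; ++a) grad[a] = lambda * w[a];
      for (int a = 0; a < m; ++a)
        for (int b = 0; b < m; ++b) G[a * m + b] = (a == b) ? lambda : 0.0;
      double gnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        if (foldid[i] == f) continue;
        double s = 0.0;
        for (int a = 0; a < m; ++a) s += Z[(size_t)a * n + i] * w[a];
        fi[i] = s;
        double margin = y[i] * s;
        if (margin < 1.0) {
          double r = 1.0 - margin;
          for (int a = 0; a < m; ++a) {
            double za = Z[(size_t)a * n + i];
            grad[a] -= 2.0 * r * y[i] * za;
            for (int b = 0; b < m; ++b)
              G[a * m + b] += 2.0 * za * Z[(size_t)b * n + i];
          }
        }
      }
      for (int a = 0; a < m; ++a) gnorm += grad[a] * grad[a];
      if (gnorm < 1e-16) break;
      if (!chol_factor(G, L, m)) return NA_REAL;
      forward_solve(L, grad, u, m);
      back_solve(L, u, d, m);
      for (int a = 0; a < m; ++a) w[a] -= d[a];
    }
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != f) continue;
      double s = 0.0;
      for (int a = 0; a < m; ++a) s += Z[(size_t)a * n + i] * w[a];
      int pred = (s >= 0.0) ? 1 : -1;
      if (pred == y[i]) ++correct;
      ++total;
    }
  }
  return (double)correct / total;
}

// [[Rcpp::export]]
List cpp_feature_bagging(NumericMatrix X, IntegerVector y, int n_draw,
                         int bag_size, int classifier,
                         Nullable<IntegerVector> foldid_, double lambda) {
  const int n = X.nrow(), p = X.ncol();
  if (bag_size < 1 || bag_size > p) stop("bag_size must lie in [1, n_features]");
  if ((int)y.size() != n) stop("label length does not match rows of X");
  const int m = bag_size + 1;

  std::vector<int> yv(n);
  for (int i = 0; i < n; ++i) {
    if (y[i] != 1 && y[i] != -1) stop("labels must be coded +1/-1");
    yv[i] = y[i];
  }

  // fold ids (0-based); empty => leave-one-out
  std::vector<int> fid(n);
  int K;
  bool loo = foldid_.isNull();
  if (loo) {
    K = n;
    for (int i = 0; i < n; ++i) fid[i] = i;
  } else {
    IntegerVector fv(foldid_);
    if ((int)fv.size() != n) stop("foldid length does not match rows of X");
    K = 0;
    for (int i = 0; i < n; ++i) {
      fid[i] = fv[i] - 1;
      if (fid[i] < 0) stop("foldid must be positive integers");
      if (fid[i] + 1 > K) K = fid[i] + 1;
    }
  }

  std::vector<double> Z((size_t)n * m);
  for (int i = 0; i < n; ++i) Z[i] = 1.0;  // intercept column
  std::vector<double> G(m * m), G0(m * m), Lc(m * m), beta(m);
  std::vector<double> work(3 * m + 2 * m * m + n + 8);
  std::vector<double> sump(m), sumc(m);
  std::vector<int> idx(p), bag(m);
  for (int j = 0; j < p; ++j) idx[j] = j;

  // per-call precomputations for the ridge LOO fast path: lower-triangular
  // packed Gram matrix (cache-resident), column sums, X'y
  const double* Xp0 = REAL(X);
  std::vector<double> gram_lt, colsum(p), xty(p);
  std::vector<size_t> rowoff(p);
  double ysum = 0.0;
  {
    for (int i = 0; i < n; ++i) ysum += y[i];
    for (int j = 0; j < p; ++j) {
      rowoff[j] = (size_t)j * (j + 1) / 2;
      const double* xj = Xp0 + (size_t)j * n;
      double cs = 0.0, xy = 0.0;
      for (int i = 0; i < n; ++i) { cs += xj[i]; xy += xj[i] * y[i]; }
      colsum[j] = cs;
      xty[j] = xy;
    }
    if (classifier == 0 && loo) {
      gram_lt.resize((size_t)p * (p + 1) / 2);
      for (int a = 0; a < p; ++a) {
        const double* xa = Xp0 + (size_t)a * n;
        for (int b = 0; b <= a; ++b) {
          const double* xb = Xp0 + (size_t)b * n;
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += xa[i] * xb[i];
          gram_lt[rowoff[a] + b] = s;
        }
      }
    }
  }

  NumericVector acc(n_draw);
  IntegerMatrix bags(n_draw, bag_size);
  const double* Xp = REAL(X);

  for (int b = 0; b < n_draw; ++b) {
    // partial Fisher-Yates draw of bag_size distinct features
    for (int k = 0; k < bag_size; ++k) {
      int j = k + (int)(unif_rand() * (p - k));
      if (j >= p) j = p - 1;
      int tmp = idx[k]; idx[k] = idx[j]; idx[j] = tmp;
      bag[k] = idx[k];
      bags(b, k) = idx[k] + 1;
      std::memcpy(&Z[(size_t)(k + 1) * n], Xp + (size_t)idx[k] * n,
                  sizeof(double) * n);
    }
    double a;
    switch (classifier) {
      case 0:
        a = (loo ? ridge_loo_accuracy(Z.data(), yv.data(), n, m, lambda,
                                      gram_lt.data(), rowoff.data(),
                                      colsum.data(), xty.data(), ysum,
                                      bag.data(), G.data(), Lc.data(),
                                      beta.data(), work.data())
                 : ridge_kfold_accuracy(Z.data(), yv.data(), n, m, lambda,
                                        fid.data(), K, G0.data(), G.data(),
                                        Lc.data(), beta.data(), work.data()));
        break;
      case 1:
        a = centroid_accuracy(Z.data(), yv.data(), n, m, fid.data(), K,
                              sump.data(), sumc.data());
        break;
      case 2:
        a = stump_accuracy(Z.data(), yv.data(), n, m, fid.data(), K,
                           sump.data(), sumc.data());
        break;
      case 3:
        a = svm_accuracy(Z.data(), yv.data(), n, m, lambda, fid.data(), K,
                         G.data(), Lc.data(), beta.data(), work.data());
        break;
      default:
        stop("unknown classifier code");
    }
    acc[b] = a;
    if (b % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["accuracy"] = acc, _["bags"] = bags);
}
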