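// Per-variant covariate-adjusted logistic regression scan.
//
// For every variant column g we fit logit P(y=1) = X b + beta_g g by IRLS
// and report the Wald statistic for beta_g (the PLINK 1.9 --logistic
// convention). Samples with a missing dosage are dropped per variant.
//
// Nested LOOCV runs this scan once per fold (~10^4 fits per cohort), so
// the inner loop is written allocation-free: the covariate-only model is
// fitted once per call, every variant fit warm-starts from it (3-4 Newton
// steps), and the normal equations are solved by a small stack Cholesky.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double kBetaTol = 1e-7;
const int kMaxQ = 64;

// Cholesky factorization A = L L' in place (lower triangle, col-major,
// leading dimension q). Returns false if A is not positive definite.
bool chol_small(double *A, int q) {
  for (int c = 0; c < q; ++c) {
    double d = A[c * q + c];
    for (int k = 0; k < c; ++k) d -= A[k * q + c] * A[k * q + c];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    A[c * q + c] = d;
    for (int r = c + 1; r < q; ++r) {
      double s = A[c * q + r];
      for (int k = 0; k < c; ++k) s -= A[k * q + r] * A[k * q + c];
      A[c * q + r] = s / d;
    }
  }
  return true;
}

// Solve L L' x = b given the factor from chol_small; b is overwritten.
void chol_solve(const double *L, int q, double *b) {
  for (int r = 0; r < q; ++r) {
    double s = b[r];
    for (int k = 0; k < r; ++k) s -= L[k * q + r] * b[k];
    b[r] = s / L[r * q + r];
  }
  for (int r = q - 1; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < q; ++k) s -= L[r * q + k] * b[k];
    b[r] = s / L[r * q + r];
  }
}

double binom_deviance(const double *eta, const double *y, int n) {
  double dev = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    if (e > 30.0) e = 30.0; else if (e < -30.0) e = -30.0;
    const double mu = 1.0 / (1.0 + std::exp(-e));
    const double m1 = std::max(mu, 1e-12), m0 = std::max(1.0 - mu, 1e-12);
    dev -= 2.0 * (y[i] * std::log(m1) + (1.0 - y[i]) * std::log(m0));
  }
  return dev;
}

// One IRLS fit over a column-major design `X` (n x q) starting from
// `beta`. On success (return 0) se_out holds the SE of coefficient q-1,
// computed from the information matrix of the final iterate, and dev_out
// the residual deviance.
int irls_dense(const double *X, int n, int q, const double *y, double *beta,
               int max_iter, double *se_out, double *dev_out, bool *converged,
               std::vector<double> &eta, std::vector<double> &w,
               std::vector<double> &wr) {
  double A[kMaxQ * kMaxQ], b[kMaxQ], L[kMaxQ * kMaxQ];
  if (q > kMaxQ) return 2;
  *converged = false;
  bool have_L = false;
  for (int it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) eta[i] = 0.0;
    for (int a = 0; a < q; ++a) {
      const double ba = beta[a];
      const double *col = X + (size_t)a * n;
      for (int i = 0; i < n; ++i) eta[i] += ba * col[i];
    }
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      if (e > 30.0) e = 30.0; else if (e < -30.0) e = -30.0;
      const double mu = 1.0 / (1.0 + std::exp(-e));
      const double wi = std::max(mu * (1.0 - mu), 1e-10);
      w[i] = wi;
      wr[i] = wi * e + (y[i] - mu);  // X' * wr = X'W z, z = eta + (y-mu)/w
    }
    for (int a = 0; a < q; ++a) {
      const double *ca = X + (size_t)a * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += ca[i] * wr[i];
      b[a] = s;
      for (int c = a; c < q; ++c) {
        const double *cc = X + (size_t)c * n;
        double t = 0.0;
        for (int i = 0; i < n; ++i) t += ca[i] * cc[i] * w[i];
        A[a * q + c] = A[c * q + a] = t;
      }
    }
    std::copy(A, A + q * q, L);
    if (!chol_small(L, q)) return 2;
    have_L = true;
    chol_solve(L, q, b);
    double delta = 0.0;
    for (int a = 0; a < q; ++a) {
      if (!std::isfinite(b[a])) return 2;
      double d = std::abs(b[a] - beta[a]);
      if (d > delta) delta = d;
      beta[a] = b[a];
    }
    if (delta < kBetaTol) {
      *converged = true;
      break;
    }
  }
  if (!have_L) return 2;
  // var(beta_{q-1}) = e_{q-1}' A^{-1} e_{q-1} via the last Cholesky factor
  // (the estimate moved < kBetaTol since that factor, so the SE is exact
  // to the same order)
  double e[kMaxQ];
  std::fill(e, e + q, 0.0);
  e[q - 1] = 1.0;
  chol_solve(L, q, e);
  const double v = e[q - 1];
  if (!std::isfinite(v) || v <= 0) return 2;
  *se_out = std::sqrt(v);
  for (int i = 0; i < n; ++i) eta[i] = 0.0;
  for (int a = 0; a < q; ++a) {
    const double ba = beta[a];
    const double *col = X + (size_t)a * n;
    for (int i = 0; i < n; ++i) eta[i] += ba * col[i];
  }
  *dev_out = binom_deviance(eta.data(), y, n);
  return 0;
}

}  // namespace

// Columns: beta, se, z, p_wald, p_lrt, status.
// Status codes: 0 = ok, 1 = not converged, 2 = unstable/separation,
// 3 = zero genotype variance, 4 = too few informative samples.
// [[Rcpp::export]]
arma::mat cpp_logistic_scan(const arma::mat &G, const arma::mat &X,
                            const arma::vec &y, int max_iter = 30) {
  const int n = (int)G.n_rows, m = (int)G.n_cols, p = (int)X.n_cols;
  const int q = p + 1;
  mat out(m, 6);
  out.fill(datum::nan);

  std::vector<double> eta(n), w(n), wr(n);

  // covariate-only warm start (genotype coefficient initialized at 0);
  // its deviance is the LRT reference for complete-data variants
  std::vector<double> beta_cov(p, 0.0);
  double dev_cov = datum::nan;
  {
    double se_dummy;
    bool conv;
    irls_dense(X.memptr(), n, p, y.memptr(), beta_cov.data(), max_iter,
               &se_dummy, &dev_cov, &conv, eta, w, wr);
  }

  // full design buffer: covariates fixed, last column swapped per variant
  mat Xf(n, q);
  Xf.cols(0, p - 1) = X;
  std::vector<double> beta(q);

  // scratch for variants with missing dosages
  mat Xs;
  std::vector<double> ys;

  for (int j = 0; j < m; ++j) {
    const double *g = G.colptr(j);
    int n_ok = 0;
    double gsum = 0.0, gsum2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (std::isfinite(g[i])) { ++n_ok; gsum += g[i]; gsum2 += g[i] * g[i]; }
    }
    if (n_ok < q + 1) { out(j, 5) = 4; continue; }
    if (gsum2 - gsum * gsum / n_ok <= 1e-12) { out(j, 5) = 3; continue; }

    const double *Xp;
    const double *yp;
    int nj;
    if (n_ok == n) {
      std::copy(g, g + n, Xf.colptr(p));
      Xp = Xf.memptr();
      yp = y.memptr();
      nj = n;
    } else {
      Xs.set_size(n_ok, q);
      ys.resize(n_ok);
      int r = 0;
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(g[i])) continue;
        for (int a = 0; a < p; ++a) Xs(r, a) = X(i, a);
        Xs(r, p) = g[i];
        ys[r] = y[i];
        ++r;
      }
      Xp = Xs.memptr();
      yp = ys.data();
      nj = n_ok;
    }
    for (int a = 0; a < p; ++a) beta[a] = beta_cov[a];
    beta[p] = 0.0;
    double se = 0.0, dev = 0.0;
    bool conv = false;
    int rc = irls_dense(Xp, nj, q, yp, beta.data(), max_iter, &se, &dev,
                        &conv, eta, w, wr);
    if (rc != 0) { out(j, 5) = 2; continue; }
    double status = conv ? 0 : 1;
    const double bg = beta[p];
    if (std::abs(bg) > 15.0 || se > 100.0) status = 2;

    double dev0 = dev_cov;
    if (nj != n) {
      // covariate-only deviance on this variant's informative subset
      std::vector<double> bc(beta_cov);
      double se0, conv_dummy_dev;
      bool conv0;
      if (irls_dense(Xp, nj, p, yp, bc.data(), max_iter, &se0,
                     &conv_dummy_dev, &conv0, eta, w, wr) == 0) {
        dev0 = conv_dummy_dev;
      } else {
        dev0 = datum::nan;
      }
    }
    const double z = bg / se;
    const double lr = dev0 - dev;
    out(j, 0) = bg;
    out(j, 1) = se;
    out(j, 2) = z;
    out(j, 3) = std::erfc(std::abs(z) / std::sqrt(2.0));
    out(j, 4) = std::isfinite(lr)
                    ? R::pchisq(std::max(lr, 0.0), 1.0, 0, 0)
                    : datum::nan;
    out(j, 5) = status;
  }
  return out;
}
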