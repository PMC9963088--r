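// Hot paths of the 1D convolution engine.
//
// Activation layout: (N*L) x C, windows stacked sample-major. Convolutions
// are computed window by window: the im2col buffer of a single window
// (L x k*C) stays cache-resident, so each layer is one small BLAS gemm per
// window instead of one huge memory-bound gemm. The stride-2 transposed
// convolution zero-stuffs its input window before the same gemm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col of one window: src points at the first sample of the window
// (column-major full matrix, column stride = ld). buf is L x (k*C).
static void window_im2col(const double* src, size_t ld, int L, int C, int k,
                          arma::mat& buf) {
  const int padL = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int shift = j - padL;
    const int t0 = std::max(0, -shift);
    const int t1 = std::min(L, L - shift) - 1;
    for (int c = 0; c < C; ++c) {
      double* dst = buf.colptr(j * C + c);
      if (t0 > 0) std::fill(dst, dst + t0, 0.0);
      if (t1 < L - 1) std::fill(dst + t1 + 1, dst + L, 0.0);
      if (t0 <= t1) {
        std::memcpy(dst + t0, src + c * ld + t0 + shift,
                    sizeof(double) * (t1 - t0 + 1));
      }
    }
  }
}

// transpose of window_im2col: scatter-add buf back into dst window
static void window_col2im(const arma::mat& buf, double* dst, size_t ld,
                          int L, int C, int k) {
  const int padL = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int shift = j - padL;
    const int t0 = std::max(0, -shift);
    const int t1 = std::min(L, L - shift) - 1;
    if (t0 > t1) continue;
    for (int c = 0; c < C; ++c) {
      const double* s = buf.colptr(j * C + c) + t0;
      double* d = dst + c * ld + t0 + shift;
      const int len = t1 - t0 + 1;
      for (int t = 0; t < len; ++t) d[t] += s[t];
    }
  }
}

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, int L, int N, const arma::mat& W,
                         const arma::vec& b) {
  const int C = X.n_cols;
  const int k = W.n_rows / C;
  const int F = W.n_cols;
  const size_t ld = X.n_rows;
  arma::mat Y(static_cast<size_t>(N) * L, F);
  arma::mat buf(L, static_cast<size_t>(k) * C);
  arma::mat Yw(L, F);
  for (int n = 0; n < N; ++n) {
    window_im2col(X.memptr() + static_cast<size_t>(n) * L, ld, L, C, k, buf);
    Yw = buf * W;
    Yw.each_row() += b.t();
    for (int f = 0; f < F; ++f) {
      std::memcpy(Y.colptr(f) + static_cast<size_t>(n) * L, Yw.colptr(f),
                  sizeof(double) * L);
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::mat& dY, const arma::mat& X, int L, int N,
                    const arma::mat& W) {
  const int C = X.n_cols;
  const int k = W.n_rows / C;
  const int F = W.n_cols;
  const size_t ldx = X.n_rows, ldy = dY.n_rows;
  arma::mat dW(W.n_rows, F, arma::fill::zeros);
  arma::mat dX(static_cast<size_t>(N) * L, C, arma::fill::zeros);
  arma::mat buf(L, static_cast<size_t>(k) * C);
  arma::mat dYw(L, F), dXcol(L, static_cast<size_t>(k) * C);
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < F; ++f) {
      std::memcpy(dYw.colptr(f), dY.colptr(f) + static_cast<size_t>(n) * L,
                  sizeof(double) * L);
    }
    window_im2col(X.memptr() + static_cast<size_t>(n) * L, ldx, L, C, k, buf);
    dW += buf.t() * dYw;
    dXcol = dYw * W.t();
    window_col2im(dXcol, dX.memptr() + static_cast<size_t>(n) * L,
                  dX.n_rows, L, C, k);
  }
  arma::rowvec db = arma::sum(dY, 0);
  (void)ldy;
  return List::create(Named("dW") = dW,
                      Named("db") = arma::vec(db.t()),
                      Named("dX") = dX);
}

// [[Rcpp::export]]
arma::mat convt1d_fwd_cpp(const arma::mat& X, int L, int N, const arma::mat& W,
                          const arma::vec& b) {
  const int C = X.n_cols;
  const int k = W.n_rows / C;
  const int F = W.n_cols;
  const int L2 = 2 * L;
  arma::mat Y(static_cast<size_t>(N) * L2, F);
  arma::mat Xu(L2, C);
  arma::mat buf(L2, static_cast<size_t>(k) * C);
  arma::mat Yw(L2, F);
  for (int n = 0; n < N; ++n) {
    Xu.zeros();
    for (int c = 0; c < C; ++c) {
      const double* s = X.colptr(c) + static_cast<size_t>(n) * L;
      double* d = Xu.colptr(c);
      for (int t = 0; t < L; ++t) d[2 * t] = s[t];
    }
    window_im2col(Xu.memptr(), Xu.n_rows, L2, C, k, buf);
    Yw = buf * W;
    Yw.each_row() += b.t();
    for (int f = 0; f < F; ++f) {
      std::memcpy(Y.colptr(f) + static_cast<size_t>(n) * L2, Yw.colptr(f),
                  sizeof(double) * L2);
    }
  }
  return Y;
}

// [[Rcpp::export]]
List convt1d_bwd_cpp(const arma::mat& dY, const arma::mat& X, int L, int N,
                     const arma::mat& W) {
  const int C = X.n_cols;
  const int k = W.n_rows / C;
  const int F = W.n_cols;
  const int L2 = 2 * L;
  arma::mat dW(W.n_rows, F, arma::fill::zeros);
  arma::mat dX(static_cast<size_t>(N) * L, C);
  arma::mat Xu(L2, C);
  arma::mat buf(L2, static_cast<size_t>(k) * C);
  arma::mat dYw(L2, F), dXcol(L2, static_cast<size_t>(k) * C);
  arma::mat dXu(L2, C);
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < F; ++f) {
      std::memcpy(dYw.colptr(f), dY.colptr(f) + static_cast<size_t>(n) * L2,
                  sizeof(double) * L2);
    }
    Xu.zeros();
    for (int c = 0; c < C; ++c) {
      const double* s = X.colptr(c) + static_cast<size_t>(n) * L;
      double* d = Xu.colptr(c);
      for (int t = 0; t < L; ++t) d[2 * t] = s[t];
    }
    window_im2col(Xu.memptr(), Xu.n_rows, L2, C, k, buf);
    dW += buf.t() * dYw;
    dXcol = dYw * W.t();
    dXu.zeros();
    window_col2im(dXcol, dXu.memptr(), dXu.n_rows, L2, C, k);
    for (int c = 0; c < C; ++c) {
      const double* s = dXu.colptr(c);
      double* d = dX.colptr(c) + static_cast<size_t>(n) * L;
      for (int t = 0; t < L; ++t) d[t] = s[2 * t];
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(Named("dW") = dW, Named("db") = arma::vec(db.t()),
                      Named("dX") = dX);
}

// fused batchnorm + leaky ReLU forward (training): returns Y, xhat, mu, var
// [[Rcpp::export]]
List bn_leaky_fwd_cpp(const arma::mat& X, const arma::vec& gamma,
                      const arma::vec& beta, double slope, double eps) {
  const int C = X.n_cols;
  const size_t n = X.n_rows;
  arma::mat Y(n, C), xhat(n, C);
  arma::vec mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double m = 0, v = 0;
    for (size_t i = 0; i < n; ++i) m += x[i];
    m /= n;
    for (size_t i = 0; i < n; ++i) { double d = x[i] - m; v += d * d; }
    v /= n;
    mu[c] = m; var[c] = v;
    const double inv_sd = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], be = beta[c];
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    for (size_t i = 0; i < n; ++i) {
      const double h = (x[i] - m) * inv_sd;
      xh[i] = h;
      const double z = g * h + be;
      y[i] = z > 0 ? z : slope * z;
    }
  }
  return List::create(Named("Y") = Y, Named("xhat") = xhat,
                      Named("mu") = mu, Named("var") = var);
}

// gradient through leaky ReLU then batchnorm (training statistics)
// [[Rcpp::export]]
List bn_leaky_bwd_cpp(const arma::mat& dA, const arma::mat& xhat,
                      const arma::vec& gamma, const arma::vec& var,
                      double slope, double eps, const arma::vec& beta) {
  const int C = dA.n_cols;
  const size_t n = dA.n_rows;
  arma::mat dX(n, C);
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* da = dA.colptr(c);
    const double* xh = xhat.colptr(c);
    const double g = gamma[c], be = beta[c];
    const double inv_sd = 1.0 / std::sqrt(var[c] + eps);
    double s_dy = 0, s_dyxh = 0;
    double* dx = dX.colptr(c);
    // first pass: gradient through the activation, accumulate channel sums
    for (size_t i = 0; i < n; ++i) {
      const double z = g * xh[i] + be; // pre-activation
      const double dy = (z > 0 ? da[i] : slope * da[i]);
      dx[i] = dy; // scratch: holds dY until the second pass
      s_dy += dy;
      s_dyxh += dy * xh[i];
    }
    dgamma[c] = s_dyxh;
    dbeta[c] = s_dy;
    const double m_dy = s_dy / n, m_dyxh = s_dyxh / n;
    const double scale = g * inv_sd;
    for (size_t i = 0; i < n; ++i) {
      dx[i] = (dx[i] - m_dy - xh[i] * m_dyxh) * scale;
    }
  }
  return List::create(Named("dX") = dX, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
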