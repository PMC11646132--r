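// 1-D convolution and max-pooling primitives for the network.
//
// Layout conventions (shared with the R layer code and the test oracles):
//   feature maps are cubes (channels, positions, batch);
//   a conv weight is a matrix (C_out, C_in * k) whose column index runs over
//   (channel fastest, kernel offset slowest), i.e. column c + C_in * t picks
//   input channel c at kernel offset t;
//   convolutions are cross-correlations (no kernel flip), zero-padded.
//
// All convolutions in the network have stride 1, which permits an im2col
// that copies one contiguous column block per kernel offset; the whole
// batch is lowered into a single matrix so each conv is one GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// write the im2col block of slice Xs into columns [off, off+Lout) of col
static void im2col_s1(const mat& Xs, int k, int pad, int Lout,
                      mat& col, int off) {
  const int C = Xs.n_rows, L = Xs.n_cols;
  for (int t = 0; t < k; ++t) {
    // output position j reads input position j + t - pad
    const int j0 = std::max(0, pad - t);
    const int j1 = std::min(Lout - 1, L - 1 + pad - t);
    if (j0 > j1) continue;
    col.submat(t * C, off + j0, (t + 1) * C - 1, off + j1) =
      Xs.cols(j0 + t - pad, j1 + t - pad);
  }
}

static mat im2col_any(const mat& Xs, int k, int pad, int stride, int Lout) {
  const int C = Xs.n_rows, L = Xs.n_cols;
  mat col(C * k, Lout, fill::zeros);
  for (int j = 0; j < Lout; ++j) {
    const int start = j * stride - pad;
    for (int t = 0; t < k; ++t) {
      const int p = start + t;
      if (p >= 0 && p < L)
        col.submat(t * C, j, (t + 1) * C - 1, j) = Xs.col(p);
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, int k, int pad, int stride) {
  const int Cin = X.n_rows, L = X.n_cols, N = X.n_slices, Cout = W.n_rows;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  cube Y(Cout, Lout, N);
  if (stride == 1) {
    mat col(Cin * k, (size_t)Lout * N, fill::zeros);
    for (int n = 0; n < N; ++n)
      im2col_s1(X.slice(n), k, pad, Lout, col, n * Lout);
    mat out = W * col;               // one GEMM for the whole batch
    out.each_col() += b;
    std::memcpy(Y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  } else {
    for (int n = 0; n < N; ++n) {
      mat col = im2col_any(X.slice(n), k, pad, stride, Lout);
      Y.slice(n) = W * col;
      Y.slice(n).each_col() += b;
    }
  }
  return Y;
}

// scatter dcol columns [off, off+Lout) back into slice dXs (stride 1)
static void col2im_s1(const mat& dcol, int k, int pad, int Lout,
                      mat& dXs, int off) {
  const int C = dXs.n_rows, L = dXs.n_cols;
  for (int t = 0; t < k; ++t) {
    const int j0 = std::max(0, pad - t);
    const int j1 = std::min(Lout - 1, L - 1 + pad - t);
    if (j0 > j1) continue;
    dXs.cols(j0 + t - pad, j1 + t - pad) +=
      dcol.submat(t * C, off + j0, (t + 1) * C - 1, off + j1);
  }
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::mat& W,
                      const arma::cube& dY, int k, int pad, int stride) {
  const int Cin = X.n_rows, L = X.n_cols, N = X.n_slices;
  const int Lout = dY.n_cols;
  cube dX(Cin, L, N, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  if (stride == 1) {
    mat col(Cin * k, (size_t)Lout * N, fill::zeros);
    for (int n = 0; n < N; ++n)
      im2col_s1(X.slice(n), k, pad, Lout, col, n * Lout);
    const mat dYmat((double*)dY.memptr(), W.n_rows, (size_t)Lout * N,
                    false, true);
    dW = dYmat * col.t();
    db = sum(dYmat, 1);
    mat dcol = W.t() * dYmat;
    for (int n = 0; n < N; ++n)
      col2im_s1(dcol, k, pad, Lout, dX.slice(n), n * Lout);
  } else {
    for (int n = 0; n < N; ++n) {
      mat col = im2col_any(X.slice(n), k, pad, stride, Lout);
      dW += dY.slice(n) * col.t();
      db += sum(dY.slice(n), 1);
      mat dcol = W.t() * dY.slice(n);
      mat& dXs = dX.slice(n);
      for (int j = 0; j < Lout; ++j) {
        const int start = j * stride - pad;
        for (int t = 0; t < k; ++t) {
          const int p = start + t;
          if (p >= 0 && p < L)
            dXs.col(p) += dcol.submat(t * Cin, j, (t + 1) * Cin - 1, j);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Max pooling with implicit -Inf padding; argmax recorded for the backward
// pass as 1-based position indices into the unpadded input.
// [[Rcpp::export(name = ".maxpool1d_fwd")]]
Rcpp::List maxpool1d_fwd(const arma::cube& X, int k, int pad, int stride) {
  const int C = X.n_rows, L = X.n_cols, N = X.n_slices;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  cube Y(C, Lout, N);
  arma::ucube amax(C, Lout, N);
  for (int n = 0; n < N; ++n) {
    const mat& Xs = X.slice(n);
    for (int j = 0; j < Lout; ++j) {
      const int start = j * stride - pad;
      const int t0 = std::max(0, start), t1 = std::min(L - 1, start + k - 1);
      for (int c = 0; c < C; ++c) {
        double best = -datum::inf; int bp = -1;
        for (int p = t0; p <= t1; ++p)
          if (Xs(c, p) > best) { best = Xs(c, p); bp = p; }
        Y(c, j, n) = best;
        amax(c, j, n) = bp + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export(name = ".maxpool1d_bwd")]]
arma::cube maxpool1d_bwd(const arma::cube& dY, const arma::ucube& amax,
                         int C, int L, int N) {
  cube dX(C, L, N, fill::zeros);
  const int Lout = dY.n_cols;
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < Lout; ++j)
      for (int c = 0; c < C; ++c) {
        const int p = (int)amax(c, j, n) - 1;
        if (p >= 0) dX(c, p, n) += dY(c, j, n);
      }
  return dX;
}

// fused ReLU helpers to avoid R-level temporaries
// [[Rcpp::export(name = ".relu_cpp")]]
arma::cube relu_cpp(const arma::cube& X) {
  cube Y = X;
  Y.for_each([](double& v) { if (v < 0) v = 0; });
  return Y;
}

// [[Rcpp::export(name = ".relu_grad_cpp")]]
arma::cube relu_grad_cpp(const arma::cube& dY, const arma::cube& Y) {
  cube dX = dY;
  const double* y = Y.memptr();
  double* d = dX.memptr();
  for (uword i = 0; i < dX.n_elem; ++i)
    if (y[i] <= 0) d[i] = 0;
  return dX;
}
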