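// Low-level kernels for the classifier's forward/backward passes.
//
// Activations travel through the network as C x (H*W*B) matrices in
// column-major order with the spatial index fastest (column n of sample b,
// position (h, w): n = (b-1)*H*W + (w-1)*H + h, 1-based in R). im2col
// unrolls receptive fields into a K x N matrix (K = kh*kw*Cin) so that a
// convolution becomes one BLAS GEMM in R; col2im scatters gradients back.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Row k of the unrolled matrix indexes (channel-fastest) the kernel tap:
// k = ((j * kh) + i) * C + c, so each (i, j) tap copies a contiguous run of
// C doubles from the input column.

// [[Rcpp::export(rng = false)]]
NumericMatrix im2col_cpp(const NumericMatrix& X, int H, int W, int B,
                         int kh, int kw, int stride, int pad) {
  const int C = X.nrow();
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  const int K = kh * kw * C;
  const int N = OH * OW * B;
  NumericMatrix out(K, N);
  const double* x = X.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const int in_off = b * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const R_xlen_t ncol_idx = (R_xlen_t)b * OH * OW + (R_xlen_t)ow * OH + oh;
        double* ocol = o + ncol_idx * K;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int j = 0; j < kw; ++j) {
          const int w = w0 + j;
          for (int i = 0; i < kh; ++i) {
            const int h = h0 + i;
            double* dst = ocol + (R_xlen_t)(j * kh + i) * C;
            if (w < 0 || w >= W || h < 0 || h >= H) {
              std::fill(dst, dst + C, 0.0);
            } else {
              const double* src = x + ((R_xlen_t)(in_off + w * H + h)) * C;
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix col2im_cpp(const NumericMatrix& Col, int C, int H, int W, int B,
                         int kh, int kw, int stride, int pad) {
  const int OH = out_dim(H, kh, stride, pad);
  const int OW = out_dim(W, kw, stride, pad);
  NumericMatrix out(C, H * W * B);
  const double* col = Col.begin();
  double* o = out.begin();
  const int K = kh * kw * C;
  for (int b = 0; b < B; ++b) {
    const int in_off = b * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const R_xlen_t ncol_idx = (R_xlen_t)b * OH * OW + (R_xlen_t)ow * OH + oh;
        const double* ccol = col + ncol_idx * K;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int j = 0; j < kw; ++j) {
          const int w = w0 + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int h = h0 + i;
            if (h < 0 || h >= H) continue;
            const double* src = ccol + (R_xlen_t)(j * kh + i) * C;
            double* dst = o + ((R_xlen_t)(in_off + w * H + h)) * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return out;
}

// Batch-normalization forward over rows (channels): one pass for the
// moments, one for the normalised output.
// [[Rcpp::export(rng = false)]]
List bn_fwd_cpp(const NumericMatrix& X, const NumericVector& gamma,
                const NumericVector& beta, double eps) {
  const int C = X.nrow();
  const R_xlen_t N = X.ncol();
  NumericVector mean(C), invstd(C);
  std::vector<double> sum(C, 0.0), sq(C, 0.0);
  const double* x = X.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* xc = x + n * C;
    for (int c = 0; c < C; ++c) { sum[c] += xc[c]; sq[c] += xc[c] * xc[c]; }
  }
  for (int c = 0; c < C; ++c) {
    mean[c] = sum[c] / N;
    double v = sq[c] / N - mean[c] * mean[c];
    if (v < 0) v = 0;
    invstd[c] = 1.0 / std::sqrt(v + eps);
  }
  NumericMatrix Y(C, N), Xhat(C, N);
  double* y = Y.begin(); double* xh = Xhat.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* xc = x + n * C;
    double* yc = y + n * C; double* hc = xh + n * C;
    for (int c = 0; c < C; ++c) {
      const double h = (xc[c] - mean[c]) * invstd[c];
      hc[c] = h;
      yc[c] = h * gamma[c] + beta[c];
    }
  }
  return List::create(_["y"] = Y, _["xhat"] = Xhat,
                      _["mean"] = mean, _["invstd"] = invstd);
}

// [[Rcpp::export(rng = false)]]
List bn_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& Xhat,
                const NumericVector& gamma, const NumericVector& invstd) {
  const int C = dY.nrow();
  const R_xlen_t N = dY.ncol();
  NumericVector dgamma(C), dbeta(C);
  const double* dy = dY.begin(); const double* xh = Xhat.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* dc = dy + n * C; const double* hc = xh + n * C;
    for (int c = 0; c < C; ++c) { dgamma[c] += dc[c] * hc[c]; dbeta[c] += dc[c]; }
  }
  NumericMatrix dX(C, N);
  double* dx = dX.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* dc = dy + n * C; const double* hc = xh + n * C;
    double* oc = dx + n * C;
    for (int c = 0; c < C; ++c) {
      const double dxhat = dc[c] * gamma[c];
      oc[c] = (invstd[c] / N) *
        (N * dxhat - dbeta[c] * gamma[c] - hc[c] * dgamma[c] * gamma[c]);
    }
  }
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix relu_fwd_cpp(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const double* x = X.begin(); double* y = Y.begin();
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return Y;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix relu_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& Y) {
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* dy = dY.begin(); const double* y = Y.begin();
  double* dx = dX.begin();
  const R_xlen_t n = (R_xlen_t)dY.nrow() * dY.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dX;
}

// column-wise scaling: Y[, n] = X[, n] * s[n] (spatial-attention broadcast)
// [[Rcpp::export(rng = false)]]
NumericMatrix scale_cols_cpp(const NumericMatrix& X, const NumericVector& s) {
  const int C = X.nrow(); const R_xlen_t N = X.ncol();
  NumericMatrix Y(C, N);
  const double* x = X.begin(); double* y = Y.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double f = s[n];
    const double* xc = x + n * C; double* yc = y + n * C;
    for (int c = 0; c < C; ++c) yc[c] = xc[c] * f;
  }
  return Y;
}

// column sums of an elementwise product (avoids the large temporary)
// [[Rcpp::export(rng = false)]]
NumericVector colsum_prod_cpp(const NumericMatrix& A, const NumericMatrix& B) {
  const int C = A.nrow(); const R_xlen_t N = A.ncol();
  NumericVector out(N);
  const double* a = A.begin(); const double* b = B.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* ac = a + n * C; const double* bc = b + n * C;
    double acc = 0;
    for (int c = 0; c < C; ++c) acc += ac[c] * bc[c];
    out[n] = acc;
  }
  return out;
}

// per-sample channel scaling: Y[, n] = X[, n] * S[, n / P]
// (channel-attention broadcast over each sample's P positions)
// [[Rcpp::export(rng = false)]]
NumericMatrix scale_cols_group_cpp(const NumericMatrix& X,
                                   const NumericMatrix& S, int P) {
  const int C = X.nrow(); const R_xlen_t N = X.ncol();
  NumericMatrix Y(C, N);
  const double* x = X.begin(); const double* s = S.begin();
  double* y = Y.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* sc = s + (n / P) * C;
    const double* xc = x + n * C; double* yc = y + n * C;
    for (int c = 0; c < C; ++c) yc[c] = xc[c] * sc[c];
  }
  return Y;
}

// per-sample row sums of an elementwise product: out[, b] = rowSums over
// sample b's positions of A * B
// [[Rcpp::export(rng = false)]]
NumericMatrix group_rowsum_prod_cpp(const NumericMatrix& A,
                                    const NumericMatrix& B, int P) {
  const int C = A.nrow(); const R_xlen_t N = A.ncol();
  const int nb = (int)(N / P);
  NumericMatrix out(C, nb);
  const double* a = A.begin(); const double* b = B.begin();
  double* o = out.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    double* oc = o + (n / P) * C;
    const double* ac = a + n * C; const double* bc = b + n * C;
    for (int c = 0; c < C; ++c) oc[c] += ac[c] * bc[c];
  }
  return out;
}

// per-column channel mean and max with argmax (spatial attention pooling)
// [[Rcpp::export(rng = false)]]
List channel_pool_cpp(const NumericMatrix& X) {
  const int C = X.nrow(); const R_xlen_t N = X.ncol();
  NumericVector avg(N), mx(N);
  IntegerVector arg(N);
  const double* x = X.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* xc = x + n * C;
    double s = xc[0], m = xc[0]; int a = 0;
    for (int c = 1; c < C; ++c) {
      s += xc[c];
      if (xc[c] > m) { m = xc[c]; a = c; }
    }
    avg[n] = s / C; mx[n] = m; arg[n] = a + 1;
  }
  return List::create(_["avg"] = avg, _["max"] = mx, _["arg"] = arg);
}

// 2-D max pooling; returns values and the 1-based linear input-column index
// of each selected element (per channel) for routing gradients back.
// [[Rcpp::export(rng = false)]]
List maxpool_cpp(const NumericMatrix& X, int H, int W, int B,
                 int k, int stride, int pad) {
  const int C = X.nrow();
  const int OH = out_dim(H, k, stride, pad);
  const int OW = out_dim(W, k, stride, pad);
  const int N = OH * OW * B;
  NumericMatrix out(C, N);
  IntegerMatrix arg(C, N);
  const double* x = X.begin();
  for (int b = 0; b < B; ++b) {
    const int in_off = b * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const R_xlen_t n = (R_xlen_t)b * OH * OW + (R_xlen_t)ow * OH + oh;
        const int h0 = oh * stride - pad;
        const int w0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          int best_idx = -1;
          for (int j = 0; j < k; ++j) {
            const int w = w0 + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int h = h0 + i;
              if (h < 0 || h >= H) continue;
              const int idx = in_off + w * H + h;
              const double v = x[(R_xlen_t)idx * C + c];
              if (v > best) { best = v; best_idx = idx; }
            }
          }
          out(c, n) = (best_idx < 0) ? 0.0 : best;
          arg(c, n) = best_idx + 1;  // 0 when the window was fully padded
        }
      }
    }
  }
  return List::create(_["values"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix maxpool_backward_cpp(const NumericMatrix& dY,
                                   const IntegerMatrix& arg,
                                   int n_in_cols) {
  const int C = dY.nrow();
  const R_xlen_t N = dY.ncol();
  NumericMatrix dX(C, n_in_cols);
  for (R_xlen_t n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const int idx = arg(c, n);
      if (idx > 0) dX(c, idx - 1) += dY(c, n);
    }
  }
  return dX;
}
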