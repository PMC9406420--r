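// Low-level tensor kernels for the SegNet building blocks.
//
// Feature maps are R arrays laid out (H, W, C, N), column-major.
// Convolution weights are (kh, kw, Cin, Cout).  Same-padding convolution is
// implemented as a "shifted-plane" im2col: the patch matrix is built
// transposed, (H*W*N) x (kh*kw*Cin), so that each column is a shifted copy
// of an input plane (contiguous segment copies), and the convolution is a
// single GEMM over the whole batch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

// dst(:, k) for k = ki + kh*(kj + kw*c) holds x shifted by the tap offset
// (rows ordered h fastest, then w, then n)
static void im2colT(const double* x, int H, int W, int C, int N,
                    int kh, int kw, int dil, arma::mat& colT) {
  const int pad_h = dil * (kh - 1) / 2;
  const int pad_w = dil * (kw - 1) / 2;
  const long HW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      const int ow = dil * kj - pad_w;
      for (int ki = 0; ki < kh; ++ki) {
        const int oh = dil * ki - pad_h;
        double* q = colT.colptr(ki + kh * (kj + (long)kw * c));
        const int h0 = std::max(0, -oh);        // dest rows receiving data
        const int h1 = std::min(H, H - oh);
        for (int n = 0; n < N; ++n) {
          const double* xp = x + HW * (c + (long)C * n);
          for (int w = 0; w < W; ++w) {
            double* seg = q + (long)H * (w + (long)W * n);
            const int ww = w + ow;
            if (ww < 0 || ww >= W || h1 <= h0) {
              std::memset(seg, 0, sizeof(double) * H);
              continue;
            }
            if (h0 > 0) std::memset(seg, 0, sizeof(double) * h0);
            if (h1 < H) std::memset(seg + h1, 0, sizeof(double) * (H - h1));
            std::memcpy(seg + h0, xp + (long)H * ww + h0 + oh,
                        sizeof(double) * (h1 - h0));
          }
        }
      }
    }
  }
}

// scatter-add the transposed patch matrix back onto the input grid
static void col2imT_add(const arma::mat& colT, int H, int W, int C, int N,
                        int kh, int kw, int dil, double* dx) {
  const int pad_h = dil * (kh - 1) / 2;
  const int pad_w = dil * (kw - 1) / 2;
  const long HW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      const int ow = dil * kj - pad_w;
      for (int ki = 0; ki < kh; ++ki) {
        const int oh = dil * ki - pad_h;
        const double* q = colT.colptr(ki + kh * (kj + (long)kw * c));
        const int h0 = std::max(0, -oh);
        const int h1 = std::min(H, H - oh);
        if (h1 <= h0) continue;
        for (int n = 0; n < N; ++n) {
          double* xp = dx + HW * (c + (long)C * n);
          for (int w = 0; w < W; ++w) {
            const int ww = w + ow;
            if (ww < 0 || ww >= W) continue;
            const double* seg = q + (long)H * (w + (long)W * n) + h0;
            double* dst = xp + (long)H * ww + h0 + oh;
            for (int h = h0; h < h1; ++h) *dst++ += *seg++;
          }
        }
      }
    }
  }
}

// (H, W, Cout, N) <-> GEMM layout (H*W*N, Cout)
static void split_rows_to_tensor(const arma::mat& Y, int H, int W, int Cout,
                                 int N, double* y) {
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      std::memcpy(y + HW * (c + (long)Cout * n),
                  Y.colptr(c) + HW * n, sizeof(double) * HW);
}

static void tensor_to_rows(const double* dy, int H, int W, int Cout, int N,
                           arma::mat& dY) {
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      std::memcpy(dY.colptr(c) + HW * n,
                  dy + HW * (c + (long)Cout * n), sizeof(double) * HW);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(const NumericVector& x, const IntegerVector& xdim,
                                 const NumericVector& w, const IntegerVector& wdim,
                                 const NumericVector& bias, int dilation) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const long HWN = (long)H * W * N;
  const arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin,
                       (size_t)Cout, false, true);
  arma::mat colT((size_t)HWN, (size_t)kh * kw * Cin, arma::fill::none);
  im2colT(x.begin(), H, W, C, N, kh, kw, dilation, colT);
  arma::mat Y = colT * Wmat;
  Y.each_row() += arma::rowvec(const_cast<double*>(bias.begin()),
                               (size_t)Cout, false, true);
  NumericVector y(Rcpp::no_init((R_xlen_t)HWN * Cout));
  split_rows_to_tensor(Y, H, W, Cout, N, y.begin());
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const NumericVector& x, const IntegerVector& xdim,
                         const NumericVector& w, const IntegerVector& wdim,
                         const NumericVector& dy, int dilation) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  const long HWN = (long)H * W * N;
  const arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin,
                       (size_t)Cout, false, true);
  arma::mat dY((size_t)HWN, (size_t)Cout, arma::fill::none);
  tensor_to_rows(dy.begin(), H, W, Cout, N, dY);
  arma::mat colT((size_t)HWN, (size_t)kh * kw * Cin, arma::fill::none);
  im2colT(x.begin(), H, W, C, N, kh, kw, dilation, colT);
  arma::mat dW = colT.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dcolT = dY * Wmat.t();
  NumericVector dx((R_xlen_t)HWN * C);  // zero-initialised
  col2imT_add(dcolT, H, W, C, N, kh, kw, dilation, dx.begin());
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2/stride-2 max pooling.  idx stores, per output cell, the argmax
// position within its window in row-major window order:
// 0 = (0,0), 1 = (0,1), 2 = (1,0), 3 = (1,1); ties keep the first.
// [[Rcpp::export]]
List cpp_maxpool(const NumericVector& x, const IntegerVector& xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("maxpool: spatial dims must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const int dr[4] = {0, 0, 1, 1};
  const int dc[4] = {0, 1, 0, 1};
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xp = x.begin() + (long)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = 2 * ho, w0 = 2 * wo;
        double best = xp[h0 + (long)H * w0];
        int bi = 0;
        for (int k = 1; k < 4; ++k) {
          const double v = xp[(h0 + dr[k]) + (long)H * (w0 + dc[k])];
          if (v > best) { best = v; bi = k; }
        }
        y[o + ho + (long)Ho * wo] = best;
        idx[o + ho + (long)Ho * wo] = bi;
      }
    }
    o += (long)Ho * Wo;
  }
  IntegerVector od = IntegerVector::create(Ho, Wo, C, N);
  y.attr("dim") = od;
  idx.attr("dim") = od;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// place pooled values back at their recorded argmax positions, zeros
// elsewhere: the decoder unpooling op, and also the gradient of max pooling
// [[Rcpp::export]]
NumericVector cpp_index_scatter(const NumericVector& p, const IntegerVector& pdim,
                                const IntegerVector& idx) {
  const int Ho = pdim[0], Wo = pdim[1], C = pdim[2], N = pdim[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector y((R_xlen_t)H * W * C * N);  // zero-initialised
  const int dr[4] = {0, 0, 1, 1};
  const int dc[4] = {0, 1, 0, 1};
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    double* yp = y.begin() + (long)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long pi = o + ho + (long)Ho * wo;
        const int k = idx[pi];
        yp[(2 * ho + dr[k]) + (long)H * (2 * wo + dc[k])] = p[pi];
      }
    }
    o += (long)Ho * Wo;
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// read the values at the recorded positions: gradient of the scatter, and
// the "re-pool" that inverts unpooling
// [[Rcpp::export]]
NumericVector cpp_index_gather(const NumericVector& x, const IntegerVector& xdim,
                               const IntegerVector& idx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector p((R_xlen_t)Ho * Wo * C * N);
  const int dr[4] = {0, 0, 1, 1};
  const int dc[4] = {0, 1, 0, 1};
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xp = x.begin() + (long)H * W * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const long pi = o + ho + (long)Ho * wo;
        const int k = idx[pi];
        p[pi] = xp[(2 * ho + dr[k]) + (long)H * (2 * wo + dc[k])];
      }
    }
    o += (long)Ho * Wo;
  }
  p.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return p;
}

// ---- batch normalization, per channel over (H, W, N) ----

// [[Rcpp::export]]
List cpp_bn_forward(const NumericVector& x, const IntegerVector& xdim,
                    const NumericVector& gamma, const NumericVector& beta,
                    double eps, bool batch_stats,
                    const NumericVector& rmean, const NumericVector& rvar) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const long HW = (long)H * W;
  const long M = HW * N;
  NumericVector mu(C), var(C);
  if (batch_stats) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + HW * (c + (long)C * n);
        for (long i = 0; i < HW; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      }
      mu[c] = s / M;
      const double v = s2 / M - mu[c] * mu[c];
      var[c] = v > 0 ? v : 0;
    }
  } else {
    mu = clone(rmean);
    var = clone(rvar);
  }
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double sc = gamma[c] / std::sqrt(var[c] + eps);
    const double sh = beta[c] - mu[c] * sc;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (long)C * n);
      double* yp = y.begin() + HW * (c + (long)C * n);
      for (long i = 0; i < HW; ++i) yp[i] = xp[i] * sc + sh;
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_backward(const NumericVector& x, const IntegerVector& xdim,
                     const NumericVector& dy, const NumericVector& gamma,
                     const NumericVector& mu, const NumericVector& var,
                     double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const long HW = (long)H * W;
  const long M = HW * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (long)C * n);
      const double* dp = dy.begin() + HW * (c + (long)C * n);
      for (long i = 0; i < HW; ++i) {
        const double xh = (xp[i] - mu[c]) * istd;
        s1 += dp[i];
        s2 += dp[i] * xh;
      }
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (long)C * n);
      const double* dp = dy.begin() + HW * (c + (long)C * n);
      double* op = dx.begin() + HW * (c + (long)C * n);
      for (long i = 0; i < HW; ++i) {
        const double xh = (xp[i] - mu[c]) * istd;
        op[i] = g * istd * (dp[i] - s1 / M - xh * s2 / M);
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- fused elementwise kernels ----

// type: 0 = relu, 1 = relu capped at 1
// [[Rcpp::export]]
NumericVector cpp_act_forward(const NumericVector& z, int type) {
  NumericVector y(Rcpp::no_init(z.size()));
  const double* zp = z.begin();
  double* yp = y.begin();
  const R_xlen_t n = z.size();
  if (type == 0) {
    for (R_xlen_t i = 0; i < n; ++i) yp[i] = zp[i] > 0 ? zp[i] : 0;
  } else {
    for (R_xlen_t i = 0; i < n; ++i)
      yp[i] = zp[i] <= 0 ? 0 : (zp[i] >= 1 ? 1 : zp[i]);
  }
  y.attr("dim") = z.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_act_backward(const NumericVector& da, const NumericVector& z,
                               int type) {
  NumericVector dz(Rcpp::no_init(da.size()));
  const double* dp = da.begin();
  const double* zp = z.begin();
  double* op = dz.begin();
  const R_xlen_t n = da.size();
  if (type == 0) {
    for (R_xlen_t i = 0; i < n; ++i) op[i] = zp[i] > 0 ? dp[i] : 0;
  } else {
    for (R_xlen_t i = 0; i < n; ++i)
      op[i] = (zp[i] > 0 && zp[i] < 1) ? dp[i] : 0;
  }
  dz.attr("dim") = da.attr("dim");
  return dz;
}

// Adam update: returns the new parameter vector; the first/second moment
// buffers are private to the optimizer state and updated in place.
// [[Rcpp::export]]
NumericVector cpp_adam_step(const NumericVector& p, const NumericVector& g,
                            NumericVector m, NumericVector v,
                            double lr, int t, double beta1, double beta2,
                            double eps) {
  NumericVector out(Rcpp::no_init(p.size()));
  const double bc1 = 1 - std::pow(beta1, t);
  const double bc2 = 1 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    m[i] = beta1 * m[i] + (1 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1 - beta2) * g[i] * g[i];
    out[i] = p[i] - lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}
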