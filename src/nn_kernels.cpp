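// Low-level convolution kernels for the network layers.
//
// Tensor layout follows R's column-major array convention throughout:
// activations are (H, W, C, N) arrays, convolution weights (k, k, Cin, Cout),
// transposed-convolution weights (k, k, Cout, Cin) (the weight of the adjoint
// convolution). All kernels are implemented as im2col / col2im plus a dense
// matrix product so the heavy lifting happens inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unroll one (H, W, C) image into a (k*k*C) x (Ho*Wo) patch matrix.
// Row index r = kh + k*kw + k*k*c matches the flattening of a (k,k,C,...)
// weight array; out-of-image taps read as zero (zero padding).
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kw - pad;
          double* dst = col.colptr(0) + r; // use (r, col) addressing below
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col(r, ho + Ho * wo) = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + kh - pad;
            col(r, ho + Ho * wo) = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
          (void)dst;
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add a patch matrix back onto an (H, W, C) image.
static void col2im_acc(const arma::mat& col, double* gx, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* gcw = gc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + kh - pad;
            if (hi >= 0 && hi < H) gcw[hi] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"); // H W C N
  IntegerVector wd = w.attr("dim"); // k k Cin Cout
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: weight expects %d input channels, got %d", wd[2], C);
  const int Ho = conv_out_size(H, k, stride, pad);
  const int Wo = conv_out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");

  arma::mat K(w.begin(), k * k * C, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat ym(y.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false, true);
    ym = col.t() * K;
    for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim"); // Ho Wo Cout N
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];

  arma::mat K(w.begin(), k * k * C, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gW((size_t)k * k * C * Cout);
  gW.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gW.begin(), k * k * C, Cout, false, true);
  arma::mat col(k * k * C, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    arma::mat gym(gy.begin() + (size_t)Ho * Wo * Cout * n, Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    gWm += col * gym;
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(gym.col(c));
    arma::mat gcol = K * gym.t(); // (k*k*C) x (Ho*Wo)
    col2im_acc(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C,
               k, stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Transposed convolution Cin -> Cout with weight (k, k, Cout, Cin):
// forward is the input-gradient pass of the adjoint convolution
// (Ho,Wo,Cout) -> (H,W,Cin).
// [[Rcpp::export]]
NumericVector convt2d_fwd_cpp(NumericVector x, NumericVector w,
                              NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"); // H W Cin N
  IntegerVector wd = w.attr("dim"); // k k Cout Cin
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  if (wd[3] != Cin) stop("convt2d: weight expects %d input channels, got %d", wd[3], Cin);
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;
  if (Ho < 1 || Wo < 1) stop("convt2d: output would be empty");

  arma::mat K(w.begin(), k * k * Cout, Cin, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  for (int n = 0; n < N; ++n) {
    arma::mat xm(x.begin() + (size_t)H * W * Cin * n, H * W, Cin, false, true);
    arma::mat gcol = K * xm.t(); // (k*k*Cout) x (H*W)
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    col2im_acc(gcol, yn, Ho, Wo, Cout, k, stride, pad, H, W);
    for (int c = 0; c < Cout; ++c) {
      double* yc = yn + (size_t)Ho * Wo * c;
      for (int i = 0; i < Ho * Wo; ++i) yc[i] += b[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List convt2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"); // H W Cin N
  IntegerVector wd = w.attr("dim"); // k k Cout Cin
  IntegerVector gd = gy.attr("dim"); // Ho Wo Cout N
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  const int Ho = gd[0], Wo = gd[1];

  arma::mat K(w.begin(), k * k * Cout, Cin, false, true);
  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = xd;
  NumericVector gW((size_t)k * k * Cout * Cin);
  gW.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gW.begin(), k * k * Cout, Cin, false, true);
  arma::mat col(k * k * Cout, H * W);

  for (int n = 0; n < N; ++n) {
    // im2col over the *output*-sized gradient image, sampled on the input grid
    im2col(gy.begin() + (size_t)Ho * Wo * Cout * n, Ho, Wo, Cout,
           k, stride, pad, H, W, col);
    arma::mat xm(x.begin() + (size_t)H * W * Cin * n, H * W, Cin, false, true);
    arma::mat gxm(gx.begin() + (size_t)H * W * Cin * n, H * W, Cin, false, true);
    gxm = col.t() * K;
    gWm += col * xm;
    const double* gyn = gy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      const double* gc = gyn + (size_t)Ho * Wo * c;
      for (int i = 0; i < Ho * Wo; ++i) gb[c] += gc[i];
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = conv_out_size(H, k, stride, pad);
  const int Wo = conv_out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // argmax as h + H*w within the slice

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride + kh - pad;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          // y is (Ho,Wo,C,N); we fill in (c,n)-major scan order, so compute index
          const size_t oi = (size_t)ho + (size_t)Ho * wo +
            (size_t)Ho * Wo * (c + (size_t)C * n);
          y[oi] = (besti >= 0) ? best : 0.0;
          idx[oi] = besti;
          ++o;
        }
      }
    }
  }
  (void)o;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector gy, IntegerVector idx,
                              int H, int W, int C, int N) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* gc = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) {
        const int bi = idx[base + i];
        if (bi >= 0) gc[bi] += gy[base + i];
      }
    }
  }
  return gx;
}
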