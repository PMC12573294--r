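// Low-level numeric kernels for 4-D activation blocks stored as R arrays with
// dim = c(N, C, H, W) (column-major, batch index fastest). Convolutions use
// im2col + BLAS GEMM over the whole batch; backward passes rebuild the column
// matrix from the saved input rather than caching it.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void check_dims4(const IntegerVector &d, const char *what) {
  if (d.size() != 4) stop("%s must be a 4-D array (N, C, H, W)", what);
  for (int i = 0; i < 4; i++)
    if (d[i] < 1) stop("%s has a zero-sized dimension", what);
}

// Fill the (N*Hout*Wout) x (Cin*k*k) column matrix. Row index is
// m = n + N*(ho + Hout*wo); column index is cin + Cin*(ki + k*kj), matching
// the flattening of a (Cout, Cin, k, k) kernel array into a Cout x (Cin*k*k)
// matrix. With rows indexed by m, the batch runs contiguously in both the
// source array and the column matrix, so the inner copy is a memcpy.
static void im2col(const double *x, int N, int C, int H, int W,
                   int k, int stride, int pad, int Hout, int Wout,
                   arma::mat &col) {
  const size_t M = (size_t)N * Hout * Wout;
  // Every (row, column) pair is written exactly once: out-of-range padded
  // patches get explicit zeros, so no upfront full-matrix clear is needed.
  for (int wo = 0; wo < Wout; wo++) {
    for (int kj = 0; kj < k; kj++) {
      int wi = wo * stride - pad + kj;
      bool wok = wi >= 0 && wi < W;
      for (int ho = 0; ho < Hout; ho++) {
        for (int ki = 0; ki < k; ki++) {
          int hi = ho * stride - pad + ki;
          bool ok = wok && hi >= 0 && hi < H;
          const size_t mbase = (size_t)N * (ho + (size_t)Hout * wo);
          for (int c = 0; c < C; c++) {
            double *dst = col.memptr() +
              M * (size_t)(c + C * (ki + k * kj)) + mbase;
            if (ok) {
              const double *src = x + (size_t)N * (c + (size_t)C * (hi + (size_t)H * wi));
              std::memcpy(dst, src, (size_t)N * sizeof(double));
            } else {
              std::memset(dst, 0, (size_t)N * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Scatter-add the (M x Cin*k*k) column-gradient matrix back onto the input
// gradient; same layout as im2col, so the inner loop is contiguous.
static void col2im_add(const arma::mat &gcol, int N, int C, int H, int W,
                       int k, int stride, int pad, int Hout, int Wout,
                       double *gx) {
  const size_t M = (size_t)N * Hout * Wout;
  for (int wo = 0; wo < Wout; wo++) {
    for (int kj = 0; kj < k; kj++) {
      int wi = wo * stride - pad + kj;
      if (wi < 0 || wi >= W) continue;
      for (int ho = 0; ho < Hout; ho++) {
        for (int ki = 0; ki < k; ki++) {
          int hi = ho * stride - pad + ki;
          if (hi < 0 || hi >= H) continue;
          const size_t mbase = (size_t)N * (ho + (size_t)Hout * wo);
          for (int c = 0; c < C; c++) {
            double *dst = gx + (size_t)N * (c + (size_t)C * (hi + (size_t)H * wi));
            const double *src = gcol.memptr() +
              M * (size_t)(c + C * (ki + k * kj)) + mbase;
            for (int n = 0; n < N; n++) dst[n] += src[n];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  check_dims4(xd, "input");
  if (wd.size() != 4) stop("kernel must be a 4-D array (Cout, Cin, k, k)");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cin = wd[1], k = wd[2];
  if (wd[3] != k) stop("kernel must be square");
  if (Cin != C) stop("kernel expects %d input channels, got %d", Cin, C);
  int Hout = conv_out_dim(H, k, stride, pad), Wout = conv_out_dim(W, k, stride, pad);
  if (Hout < 1 || Wout < 1) stop("spatial input too small for this kernel/stride/padding");

  const size_t M = (size_t)N * Hout * Wout;
  arma::mat col(M, (size_t)Cin * k * k, arma::fill::none);
  im2col(x.begin(), N, C, H, W, k, stride, pad, Hout, Wout, col);
  arma::mat Wm(const_cast<double *>(w.begin()), Cout, (size_t)Cin * k * k, false, true);
  arma::mat Y = col * Wm.t(); // M x Cout

  NumericVector y((size_t)N * Cout * Hout * Wout);
  y.attr("dim") = IntegerVector::create(N, Cout, Hout, Wout);
  const double *bp = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bp = bv.begin(); }
  double *yp = y.begin();
  const size_t HWo = (size_t)Hout * Wout;
  for (int co = 0; co < Cout; co++) {
    const double *src = Y.colptr(co);
    const double bco = bp ? bp[co] : 0.0;
    for (size_t hw = 0; hw < HWo; hw++) {
      double *dst = yp + (size_t)N * (co + (size_t)Cout * hw);
      const double *s = src + (size_t)N * hw;
      for (int n = 0; n < N; n++) dst[n] = s[n] + bco;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool need_gx, bool need_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cin = wd[1], k = wd[2];
  int Hout = gd[2], Wout = gd[3];
  const size_t M = (size_t)N * Hout * Wout;

  // gather gy into M x Cout (batch contiguous in both source and target)
  arma::mat Gy(M, Cout, arma::fill::none);
  const double *gp = gy.begin();
  const size_t HWo = (size_t)Hout * Wout;
  for (int co = 0; co < Cout; co++) {
    double *dst = Gy.colptr(co);
    for (size_t hw = 0; hw < HWo; hw++)
      std::memcpy(dst + (size_t)N * hw,
                  gp + (size_t)N * (co + (size_t)Cout * hw),
                  (size_t)N * sizeof(double));
  }

  arma::mat col(M, (size_t)Cin * k * k, arma::fill::none);
  im2col(x.begin(), N, C, H, W, k, stride, pad, Hout, Wout, col);

  arma::mat Gw = Gy.t() * col; // Cout x CinKK
  NumericVector gw(Gw.n_elem);
  std::copy(Gw.memptr(), Gw.memptr() + Gw.n_elem, gw.begin());
  gw.attr("dim") = IntegerVector::create(Cout, Cin, k, k);

  List out = List::create(Named("gw") = gw);
  if (need_bias) {
    arma::rowvec gb = arma::sum(Gy, 0);
    out["gb"] = NumericVector(gb.begin(), gb.end());
  }
  if (need_gx) {
    arma::mat Wm(const_cast<double *>(w.begin()), Cout, (size_t)Cin * k * k, false, true);
    arma::mat Gcol = Gy * Wm; // M x CinKK
    NumericVector gx((size_t)N * C * H * W);
    gx.attr("dim") = IntegerVector::create(N, C, H, W);
    col2im_add(Gcol, N, C, H, W, k, stride, pad, Hout, Wout, gx.begin());
    out["gx"] = gx;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool2d_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  check_dims4(xd, "input");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Hout = conv_out_dim(H, k, stride, pad), Wout = conv_out_dim(W, k, stride, pad);
  if (Hout < 1 || Wout < 1) stop("spatial input too small for this pooling window");
  NumericVector y((size_t)N * C * Hout * Wout);
  y.attr("dim") = IntegerVector::create(N, C, Hout, Wout);
  IntegerVector amax(y.size()); // 0-based linear index into x
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = amax.begin();
  for (int wo = 0; wo < Wout; wo++)
    for (int ho = 0; ho < Hout; ho++)
      for (int c = 0; c < C; c++)
        for (int n = 0; n < N; n++) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int kj = 0; kj < k; kj++) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ki++) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              size_t off = n + (size_t)N * (c + (size_t)C * (hi + (size_t)H * wi));
              if (xp[off] > best) { best = xp[off]; besti = off; }
            }
          }
          size_t oo = n + (size_t)N * (c + (size_t)C * (ho + (size_t)Hout * wo));
          yp[oo] = best;
          ap[oo] = (int)besti;
        }
  return List::create(Named("y") = y, Named("argmax") = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2d_bwd(NumericVector gy, IntegerVector amax, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double *gp = gx.begin();
  const double *gyp = gy.begin();
  const int *ap = amax.begin();
  for (R_xlen_t i = 0; i < gy.size(); i++) gp[ap[i]] += gyp[i];
  return gx;
}

// Z-pool: channel 1 = per-position max over channels, channel 2 = mean.
// [[Rcpp::export]]
List cpp_zpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  check_dims4(xd, "input");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((size_t)N * 2 * H * W);
  y.attr("dim") = IntegerVector::create(N, 2, H, W);
  IntegerVector amax((size_t)N * H * W); // winning channel, 0-based
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = amax.begin();
  for (size_t hw = 0; hw < (size_t)H * W; hw++)
    for (int n = 0; n < N; n++) {
      double best = -std::numeric_limits<double>::infinity(), acc = 0;
      int bc = 0;
      for (int c = 0; c < C; c++) {
        double v = xp[n + (size_t)N * (c + (size_t)C * hw)];
        acc += v;
        if (v > best) { best = v; bc = c; }
      }
      yp[n + (size_t)N * (0 + 2 * hw)] = best;
      yp[n + (size_t)N * (1 + 2 * hw)] = acc / C;
      ap[n + (size_t)N * hw] = bc;
    }
  return List::create(Named("y") = y, Named("argmax") = amax);
}

// [[Rcpp::export]]
NumericVector cpp_zpool_bwd(NumericVector gy, IntegerVector amax, int C) {
  IntegerVector gd = gy.attr("dim");
  int N = gd[0], H = gd[2], W = gd[3];
  NumericVector gx((size_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  const double *gp = gy.begin();
  const int *ap = amax.begin();
  double *op = gx.begin();
  for (size_t hw = 0; hw < (size_t)H * W; hw++)
    for (int n = 0; n < N; n++) {
      double gmaxv = gp[n + (size_t)N * (0 + 2 * hw)];
      double gmean = gp[n + (size_t)N * (1 + 2 * hw)] / C;
      for (int c = 0; c < C; c++)
        op[n + (size_t)N * (c + (size_t)C * hw)] += gmean;
      op[n + (size_t)N * (ap[n + (size_t)N * hw] + (size_t)C * hw)] += gmaxv;
    }
  return gx;
}

// Global spatial max pooling: (N,C,H,W) -> (N,C) with 0-based linear argmax.
// [[Rcpp::export]]
List cpp_gmp_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  check_dims4(xd, "input");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericMatrix y(N, C);
  IntegerVector amax((size_t)N * C);
  const double *xp = x.begin();
  int *ap = amax.begin();
  for (int c = 0; c < C; c++)
    for (int n = 0; n < N; n++) {
      double best = -std::numeric_limits<double>::infinity();
      size_t besti = 0;
      for (size_t hw = 0; hw < (size_t)H * W; hw++) {
        size_t off = n + (size_t)N * (c + (size_t)C * hw);
        if (xp[off] > best) { best = xp[off]; besti = off; }
      }
      y(n, c) = best;
      ap[n + (size_t)N * c] = (int)besti;
    }
  return List::create(Named("y") = y, Named("argmax") = amax);
}

// Elementwise ReLU; backward masks the upstream gradient by y > 0.
// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = x.begin();
  double *yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); i++) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector y) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const double *gp = g.begin(), *yp = y.begin();
  double *op = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); i++) op[i] = yp[i] > 0 ? gp[i] : 0.0;
  return gx;
}

// Per-channel batch statistics over (N, H, W): two-pass mean and biased
// variance, fused in C++ to avoid full-size temporaries.
// [[Rcpp::export]]
List cpp_bn2d_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  check_dims4(xd, "input");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)N * HW;
  NumericVector mu(C), var(C);
  const double *xp = x.begin();
  for (size_t hw = 0; hw < HW; hw++)
    for (int c = 0; c < C; c++) {
      const double *p = xp + (size_t)N * (c + (size_t)C * hw);
      double acc = 0;
      for (int n = 0; n < N; n++) acc += p[n];
      mu[c] += acc;
    }
  for (int c = 0; c < C; c++) mu[c] /= m;
  for (size_t hw = 0; hw < HW; hw++)
    for (int c = 0; c < C; c++) {
      const double *p = xp + (size_t)N * (c + (size_t)C * hw);
      const double mc = mu[c];
      double acc = 0;
      for (int n = 0; n < N; n++) { double d = p[n] - mc; acc += d * d; }
      var[c] += acc;
    }
  for (int c = 0; c < C; c++) var[c] /= m;
  return List::create(Named("mean") = mu, Named("var") = var);
}

// y = gamma * (x - mean) * invstd + beta, per channel, in one pass.
// [[Rcpp::export]]
NumericVector cpp_bn2d_fwd(NumericVector x, NumericVector mean,
                           NumericVector invstd, NumericVector gamma,
                           NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  check_dims4(xd, "input");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double *xp = x.begin();
  double *yp = y.begin();
  for (size_t hw = 0; hw < HW; hw++)
    for (int c = 0; c < C; c++) {
      const double a = gamma[c] * invstd[c];
      const double b = beta[c] - mean[c] * a;
      const double *p = xp + (size_t)N * (c + (size_t)C * hw);
      double *q = yp + (size_t)N * (c + (size_t)C * hw);
      for (int n = 0; n < N; n++) q[n] = a * p[n] + b;
    }
  return y;
}

// Batch-norm backward. Pass 1 accumulates dgamma = sum(g * xhat) and
// dbeta = sum(g) per channel; with dxhat = g * gamma this also gives
// sum(dxhat) = gamma * dbeta and sum(dxhat * xhat) = gamma * dgamma, so in
// training mode pass 2 forms
//   gx = invstd * (dxhat - (xhat * sum(dxhat * xhat) + sum(dxhat)) / m)
// and in eval mode gx = g * gamma * invstd.
// [[Rcpp::export]]
List cpp_bn2d_bwd(NumericVector x, NumericVector g, NumericVector gamma,
                  NumericVector mean, NumericVector invstd, bool training,
                  bool need_gx) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)N * HW;
  NumericVector dgamma(C), dbeta(C);
  const double *xp = x.begin(), *gp = g.begin();
  for (size_t hw = 0; hw < HW; hw++)
    for (int c = 0; c < C; c++) {
      const size_t off = (size_t)N * (c + (size_t)C * hw);
      const double *px = xp + off, *pg = gp + off;
      const double mc = mean[c], ic = invstd[c];
      double accg = 0, accb = 0;
      for (int n = 0; n < N; n++) {
        accg += pg[n] * (px[n] - mc) * ic;
        accb += pg[n];
      }
      dgamma[c] += accg;
      dbeta[c] += accb;
    }
  List out = List::create(Named("dgamma") = dgamma, Named("dbeta") = dbeta);
  if (need_gx) {
    NumericVector gx(x.size());
    gx.attr("dim") = xd;
    double *op = gx.begin();
    for (size_t hw = 0; hw < HW; hw++)
      for (int c = 0; c < C; c++) {
        const size_t off = (size_t)N * (c + (size_t)C * hw);
        const double *px = xp + off, *pg = gp + off;
        double *q = op + off;
        const double gc = gamma[c], mc = mean[c], ic = invstd[c];
        if (training) {
          const double s1 = gc * dbeta[c] / m, s2 = gc * dgamma[c] / m;
          for (int n = 0; n < N; n++) {
            const double xhat = (px[n] - mc) * ic;
            q[n] = ic * (pg[n] * gc - xhat * s2 - s1);
          }
        } else {
          const double a = gc * ic;
          for (int n = 0; n < N; n++) q[n] = pg[n] * a;
        }
      }
    out["gx"] = gx;
  }
  return out;
}

// Forward convolution that additionally returns the im2col matrix as an
// external pointer, so the backward pass can reuse it instead of rebuilding.
// [[Rcpp::export]]
List cpp_conv2d_fwd_cache(NumericVector x, NumericVector w,
                          Nullable<NumericVector> bias,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  check_dims4(xd, "input");
  if (wd.size() != 4) stop("kernel must be a 4-D array (Cout, Cin, k, k)");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], Cin = wd[1], k = wd[2];
  if (wd[3] != k) stop("kernel must be square");
  if (Cin != C) stop("kernel expects %d input channels, got %d", Cin, C);
  int Hout = conv_out_dim(H, k, stride, pad), Wout = conv_out_dim(W, k, stride, pad);
  if (Hout < 1 || Wout < 1) stop("spatial input too small for this kernel/stride/padding");

  const size_t M = (size_t)N * Hout * Wout;
  XPtr<arma::mat> colp(new arma::mat(M, (size_t)Cin * k * k, arma::fill::none), true);
  im2col(x.begin(), N, C, H, W, k, stride, pad, Hout, Wout, *colp);
  arma::mat Wm(const_cast<double *>(w.begin()), Cout, (size_t)Cin * k * k, false, true);
  arma::mat Y = (*colp) * Wm.t(); // M x Cout

  NumericVector y((size_t)N * Cout * Hout * Wout);
  y.attr("dim") = IntegerVector::create(N, Cout, Hout, Wout);
  const double *bp = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bp = bv.begin(); }
  double *yp = y.begin();
  const size_t HWo = (size_t)Hout * Wout;
  for (int co = 0; co < Cout; co++) {
    const double *src = Y.colptr(co);
    const double bco = bp ? bp[co] : 0.0;
    for (size_t hw = 0; hw < HWo; hw++) {
      double *dst = yp + (size_t)N * (co + (size_t)Cout * hw);
      const double *s = src + (size_t)N * hw;
      for (int n = 0; n < N; n++) dst[n] = s[n] + bco;
    }
  }
  return List::create(Named("y") = y, Named("col") = colp);
}

// Backward convolution against a cached im2col matrix.
// [[Rcpp::export]]
List cpp_conv2d_bwd_cache(SEXP colptr, NumericVector w, NumericVector gy,
                          IntegerVector xdim, int stride, int pad,
                          bool need_gx, bool need_bias) {
  XPtr<arma::mat> colp(colptr);
  arma::mat &col = *colp;
  IntegerVector wd = w.attr("dim"), gd = gy.attr("dim");
  int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  int Cout = wd[0], Cin = wd[1], k = wd[2];
  int Hout = gd[2], Wout = gd[3];
  const size_t M = (size_t)N * Hout * Wout;
  if (col.n_rows != M || col.n_cols != (size_t)Cin * k * k)
    stop("cached im2col matrix does not match this convolution");

  arma::mat Gy(M, Cout, arma::fill::none);
  const double *gp = gy.begin();
  const size_t HWo = (size_t)Hout * Wout;
  for (int co = 0; co < Cout; co++) {
    double *dst = Gy.colptr(co);
    for (size_t hw = 0; hw < HWo; hw++)
      std::memcpy(dst + (size_t)N * hw,
                  gp + (size_t)N * (co + (size_t)Cout * hw),
                  (size_t)N * sizeof(double));
  }

  arma::mat Gw = Gy.t() * col; // Cout x CinKK
  NumericVector gw(Gw.n_elem);
  std::copy(Gw.memptr(), Gw.memptr() + Gw.n_elem, gw.begin());
  gw.attr("dim") = IntegerVector::create(Cout, Cin, k, k);

  List out = List::create(Named("gw") = gw);
  if (need_bias) {
    arma::rowvec gb = arma::sum(Gy, 0);
    out["gb"] = NumericVector(gb.begin(), gb.end());
  }
  if (need_gx) {
    arma::mat Wm(const_cast<double *>(w.begin()), Cout, (size_t)Cin * k * k, false, true);
    arma::mat Gcol = Gy * Wm; // M x CinKK
    NumericVector gx((size_t)N * C * H * W);
    gx.attr("dim") = IntegerVector::create(N, C, H, W);
    col2im_add(Gcol, N, C, H, W, k, stride, pad, Hout, Wout, gx.begin());
    out["gx"] = gx;
  }
  // drop the cached matrix storage now; the XPtr finalizer deletes the
  // (now empty) object when the R reference is collected
  col.reset();
  return out;
}

// 4-D permutation (1-based perm, like aperm). perm[0] must be 1, which all
// call sites satisfy (the batch axis stays first), so the inner copy over
// the batch is contiguous in both source and target.
// [[Rcpp::export]]
NumericVector cpp_aperm4(NumericVector x, IntegerVector perm) {
  IntegerVector xd = x.attr("dim");
  check_dims4(xd, "input");
  if (perm.size() != 4 || perm[0] != 1) stop("perm must be 4-long and keep axis 1 first");
  int d1 = xd[perm[1] - 1], d2 = xd[perm[2] - 1], d3 = xd[perm[3] - 1];
  int N = xd[0];
  size_t xstr[4] = {1, (size_t)xd[0], (size_t)xd[0] * xd[1],
                    (size_t)xd[0] * xd[1] * xd[2]};
  size_t s1 = xstr[perm[1] - 1], s2 = xstr[perm[2] - 1], s3 = xstr[perm[3] - 1];
  NumericVector y(x.size());
  y.attr("dim") = IntegerVector::create(N, d1, d2, d3);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int i3 = 0; i3 < d3; i3++)
    for (int i2 = 0; i2 < d2; i2++)
      for (int i1 = 0; i1 < d1; i1++) {
        const double *src = xp + s1 * i1 + s2 * i2 + s3 * i3;
        std::memcpy(yp, src, (size_t)N * sizeof(double));
        yp += N;
      }
  return y;
}

// Per-position gate: y[n,c,p] = x[n,c,p] * g[n,p] with g of shape (N,1,H,W).
// [[Rcpp::export]]
NumericVector cpp_sgate_fwd(NumericVector x, NumericVector g) {
  IntegerVector xd = x.attr("dim");
  check_dims4(xd, "input");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double *xp = x.begin(), *gp = g.begin();
  double *yp = y.begin();
  for (size_t hw = 0; hw < HW; hw++) {
    const double *gv = gp + (size_t)N * hw;
    for (int c = 0; c < C; c++) {
      const size_t off = (size_t)N * (c + (size_t)C * hw);
      for (int n = 0; n < N; n++) yp[off + n] = xp[off + n] * gv[n];
    }
  }
  return y;
}

// Backward of the per-position gate: gx = gr * g (broadcast over channels),
// gg[n,p] = sum_c gr[n,c,p] * x[n,c,p].
// [[Rcpp::export]]
List cpp_sgate_bwd(NumericVector x, NumericVector g, NumericVector gr,
                   bool need_gx) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector gg((size_t)N * HW);
  gg.attr("dim") = IntegerVector::create(N, 1, H, W);
  const double *xp = x.begin(), *gp = g.begin(), *rp = gr.begin();
  double *ggp = gg.begin();
  NumericVector gx;
  double *gxp = nullptr;
  if (need_gx) {
    gx = NumericVector(x.size());
    gx.attr("dim") = xd;
    gxp = gx.begin();
  }
  for (size_t hw = 0; hw < HW; hw++) {
    const double *gv = gp + (size_t)N * hw;
    double *ga = ggp + (size_t)N * hw;
    for (int c = 0; c < C; c++) {
      const size_t off = (size_t)N * (c + (size_t)C * hw);
      for (int n = 0; n < N; n++) {
        ga[n] += rp[off + n] * xp[off + n];
        if (gxp) gxp[off + n] = rp[off + n] * gv[n];
      }
    }
  }
  List out = List::create(Named("gg") = gg);
  if (need_gx) out["gx"] = gx;
  return out;
}
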