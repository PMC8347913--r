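// Minimal conv-net primitives for small dilated-convolution regression
// networks: 2-D convolution (arbitrary dilation, zero padding) via
// im2col + GEMM, and 2x2/stride-2 max pooling with argmax bookkeeping.
// Arrays follow R's column-major layout with dimensions (H, W, C, N).
// The im2col buffer is kept transposed (patch index down the column) so
// both its fill and the GEMM run over unit-stride memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::uword idx4(arma::uword h, arma::uword w, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return h + H * (w + W * (c + C * n));
}

// Fill rows [n*Ho*Wo, (n+1)*Ho*Wo) of the transposed im2col matrix
// (Ho*Wo*N x k*k*Cin) for sample n.
static void im2col_t(const double *x, arma::uword H, arma::uword W,
                     arma::uword Cin, arma::uword n, int k, int d, int pad,
                     arma::uword Ho, arma::uword Wo, arma::mat &XcT) {
  const arma::uword roff = n * Ho * Wo;
  for (arma::uword ci = 0; ci < Cin; ++ci)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = ki + k * (kj + k * ci);
        double *dst = XcT.colptr(col) + roff;
        for (arma::uword wo = 0; wo < Wo; ++wo) {
          const long wi = (long)wo - pad + (long)kj * d;
          double *dcol = dst + Ho * wo;
          if (wi < 0 || wi >= (long)W) {
            std::fill(dcol, dcol + Ho, 0.0);
            continue;
          }
          const long h0 = -(long)pad + (long)ki * d;  // input h at ho = 0
          const double *src = x + idx4(0, (arma::uword)wi, ci, n, H, W, Cin);
          for (arma::uword ho = 0; ho < Ho; ++ho) {
            const long hi = h0 + (long)ho;
            dcol[ho] = (hi >= 0 && hi < (long)H) ? src[hi] : 0.0;
          }
        }
      }
}

// Scatter-add the transposed column gradient back onto sample n of dx.
static void col2im_t(const arma::mat &dXcT, double *dx, arma::uword H,
                     arma::uword W, arma::uword Cin, arma::uword n, int k,
                     int d, int pad, arma::uword Ho, arma::uword Wo) {
  const arma::uword roff = n * Ho * Wo;
  for (arma::uword ci = 0; ci < Cin; ++ci)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword col = ki + k * (kj + k * ci);
        const double *src0 = dXcT.colptr(col) + roff;
        for (arma::uword wo = 0; wo < Wo; ++wo) {
          const long wi = (long)wo - pad + (long)kj * d;
          if (wi < 0 || wi >= (long)W) continue;
          const long h0 = -(long)pad + (long)ki * d;
          double *dst = dx + idx4(0, (arma::uword)wi, ci, n, H, W, Cin);
          const double *src = src0 + Ho * wo;
          const long lo = std::max(0L, -h0);
          const long hi = std::min((long)Ho, (long)H - h0);
          for (long ho = lo; ho < hi; ++ho) dst[h0 + ho] += src[ho];
        }
      }
}

// Weight tensor (k, k, Cin, Cout) flattened to (k*k*Cin x Cout).
static arma::mat weight_matrix(const NumericVector &w, int k, arma::uword Cin,
                               arma::uword Cout) {
  return arma::mat(const_cast<double *>(w.begin()), (arma::uword)k * k * Cin,
                   Cout, /*copy*/ true);
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
List conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                int dilation, int pad, bool relu, bool keep_cache) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0];
  const arma::uword Cout = wd[3];
  const int ke = (k - 1) * dilation + 1;
  const long Ho_ = (long)H + 2 * pad - ke + 1, Wo_ = (long)W + 2 * pad - ke + 1;
  if (Ho_ < 1 || Wo_ < 1)
    stop("effective kernel extent (%d) exceeds feature map size (%d x %d)", ke,
         (int)H, (int)W);
  const arma::uword Ho = Ho_, Wo = Wo_;

  arma::mat Wm = weight_matrix(w, k, Cin, Cout);
  arma::mat XcT(Ho * Wo * N, (arma::uword)k * k * Cin);
  for (arma::uword n = 0; n < N; ++n)
    im2col_t(x.begin(), H, W, Cin, n, k, dilation, pad, Ho, Wo, XcT);
  arma::mat Y = XcT * Wm;  // (Ho*Wo*N x Cout)

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double *yp = y.begin();
  const arma::uword P = Ho * Wo;
  for (arma::uword co = 0; co < Cout; ++co) {
    const double bc = b[co];
    const double *src = Y.colptr(co);
    for (arma::uword n = 0; n < N; ++n) {
      double *dst = yp + P * (co + Cout * n);
      const double *s = src + P * n;
      if (relu)
        for (arma::uword p = 0; p < P; ++p) {
          const double v = s[p] + bc;
          dst[p] = v > 0 ? v : 0;
        }
      else
        for (arma::uword p = 0; p < P; ++p) dst[p] = s[p] + bc;
    }
  }
  if (keep_cache) {
    XPtr<arma::mat> cache(new arma::mat(std::move(XcT)), true);
    return List::create(_["y"] = y, _["cache"] = cache);
  }
  return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                NumericVector y, int dilation, int pad, bool relu,
                SEXP cache, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const arma::uword H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0];
  const arma::uword Cout = wd[3];
  const arma::uword Ho = yd[0], Wo = yd[1], P = Ho * Wo;

  // dY in (Ho*Wo*N x Cout) layout, ReLU-gated by the stored activations.
  arma::mat dY(P * N, Cout);
  const double *dyp = dy.begin(), *yp = y.begin();
  for (arma::uword co = 0; co < Cout; ++co) {
    double *dst = dY.colptr(co);
    for (arma::uword n = 0; n < N; ++n) {
      const arma::uword off = P * (co + Cout * n);
      double *d = dst + P * n;
      if (relu)
        for (arma::uword p = 0; p < P; ++p)
          d[p] = yp[off + p] > 0 ? dyp[off + p] : 0.0;
      else
        for (arma::uword p = 0; p < P; ++p) d[p] = dyp[off + p];
    }
  }

  arma::mat dWm;
  if (cache != R_NilValue) {
    XPtr<arma::mat> xc(cache);
    dWm = xc->t() * dY;
  } else {
    arma::mat XcT(P * N, (arma::uword)k * k * Cin);
    for (arma::uword n = 0; n < N; ++n)
      im2col_t(x.begin(), H, W, Cin, n, k, dilation, pad, Ho, Wo, XcT);
    dWm = XcT.t() * dY;                  // (k*k*Cin x Cout)
  }
  arma::rowvec db = arma::sum(dY, 0);

  NumericVector dx(need_dx ? (R_xlen_t)H * W * Cin * N : 0);
  if (need_dx) {
    arma::mat Wm = weight_matrix(w, k, Cin, Cout);
    arma::mat dXcT = dY * Wm.t();        // (Ho*Wo*N x k*k*Cin)
    dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
    for (arma::uword n = 0; n < N; ++n)
      col2im_t(dXcT, dx.begin(), H, W, Cin, n, k, dilation, pad, Ho, Wo);
  }

  NumericVector dw(wd[0] * wd[1] * wd[2] * wd[3]);
  dw.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector am((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  am.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword wo = 0; wo < Wo; ++wo)
        for (arma::uword ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL;
          arma::uword bi = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              const arma::uword li =
                  idx4(2 * ho + dh, 2 * wo + dw2, c, n, H, W, C);
              if (xp[li] > best) { best = xp[li]; bi = li; }
            }
          const arma::uword lo = idx4(ho, wo, c, n, Ho, Wo, C);
          y[lo] = best;
          am[lo] = (int)(bi + 1);  // 1-based for R indexing
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}
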