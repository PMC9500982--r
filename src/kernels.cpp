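// Numeric kernels for the 3D CNN engine: zero-padded strided 3D convolution
// and 3D max pooling, forward and backward. Tensors are R arrays with dim
// (N, C, D, H, W) in R's column-major layout; index arithmetic below mirrors
// that layout exactly.

#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t idx5(int n, int c, int d, int h, int w,
                            int N, int C, int D, int H) {
  return n + (R_xlen_t)N * (c + (R_xlen_t)C * (d + (R_xlen_t)D * (h + (R_xlen_t)H * w)));
}

// weight layout: dim (Co, Ci, Kd, Kh, Kw), column-major
static inline R_xlen_t widx(int co, int ci, int kd, int kh, int kw,
                            int Co, int Ci, int Kd, int Kh) {
  return co + (R_xlen_t)Co * (ci + (R_xlen_t)Ci * (kd + (R_xlen_t)Kd * (kh + (R_xlen_t)Kh * kw)));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector bias,
                         IntegerVector stride, IntegerVector pad) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int Co = wdim[0], Ci = wdim[1], Kd = wdim[2], Kh = wdim[3], Kw = wdim[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  if (Ci != C) stop("conv3d: channel mismatch");
  const int Do = (D + 2 * pd - Kd) / sd + 1;
  const int Ho = (H + 2 * ph - Kh) / sh + 1;
  const int Wo = (W + 2 * pw - Kw) / sw + 1;
  NumericVector y((R_xlen_t)N * Co * Do * Ho * Wo);
  const bool has_bias = bias.size() == Co;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int dO = 0; dO < Do; ++dO)
        for (int co = 0; co < Co; ++co)
          for (int n = 0; n < N; ++n) {
            double acc = has_bias ? bias[co] : 0.0;
            for (int kw = 0; kw < Kw; ++kw) {
              const int wi = wo * sw - pw + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < Kh; ++kh) {
                const int hi = ho * sh - ph + kh;
                if (hi < 0 || hi >= H) continue;
                for (int kd = 0; kd < Kd; ++kd) {
                  const int di = dO * sd - pd + kd;
                  if (di < 0 || di >= D) continue;
                  for (int ci = 0; ci < C; ++ci) {
                    acc += x[idx5(n, ci, di, hi, wi, N, C, D, H)] *
                           w[widx(co, ci, kd, kh, kw, Co, Ci, Kd, Kh)];
                  }
                }
              }
            }
            y[idx5(n, co, dO, ho, wo, N, Co, Do, Ho)] = acc;
          }
  y.attr("dim") = IntegerVector::create(N, Co, Do, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector dy, IntegerVector ydim,
                IntegerVector stride, IntegerVector pad,
                bool has_bias) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int Co = wdim[0], Ci = wdim[1], Kd = wdim[2], Kh = wdim[3], Kw = wdim[4];
  const int Do = ydim[2], Ho = ydim[3], Wo = ydim[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(has_bias ? Co : 0);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int dO = 0; dO < Do; ++dO)
        for (int co = 0; co < Co; ++co)
          for (int n = 0; n < N; ++n) {
            const double g = dy[idx5(n, co, dO, ho, wo, N, Co, Do, Ho)];
            if (g == 0.0) continue;
            if (has_bias) db[co] += g;
            for (int kw = 0; kw < Kw; ++kw) {
              const int wi = wo * sw - pw + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < Kh; ++kh) {
                const int hi = ho * sh - ph + kh;
                if (hi < 0 || hi >= H) continue;
                for (int kd = 0; kd < Kd; ++kd) {
                  const int di = dO * sd - pd + kd;
                  if (di < 0 || di >= D) continue;
                  for (int ci = 0; ci < C; ++ci) {
                    const R_xlen_t xi = idx5(n, ci, di, hi, wi, N, C, D, H);
                    const R_xlen_t wi2 = widx(co, ci, kd, kh, kw, Co, Ci, Kd, Kh);
                    dx[xi] += g * w[wi2];
                    dw[wi2] += g * x[xi];
                  }
                }
              }
            }
          }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, IntegerVector xdim,
                   IntegerVector kernel, IntegerVector stride) {
  const int N = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3], W = xdim[4];
  const int Kd = kernel[0], Kh = kernel[1], Kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int Do = (D - Kd) / sd + 1;
  const int Ho = (H - Kh) / sh + 1;
  const int Wo = (W - Kw) / sw + 1;
  NumericVector y((R_xlen_t)N * C * Do * Ho * Wo);
  NumericVector arg(y.size());  // 0-based linear index into x (double: may exceed int)
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int dO = 0; dO < Do; ++dO)
        for (int c = 0; c < C; ++c)
          for (int n = 0; n < N; ++n) {
            double best = R_NegInf;
            R_xlen_t best_i = -1;
            for (int kw = 0; kw < Kw; ++kw)
              for (int kh = 0; kh < Kh; ++kh)
                for (int kd = 0; kd < Kd; ++kd) {
                  const R_xlen_t xi = idx5(n, c, dO * sd + kd, ho * sh + kh,
                                           wo * sw + kw, N, C, D, H);
                  if (x[xi] > best) { best = x[xi]; best_i = xi; }
                }
            const R_xlen_t yi = idx5(n, c, dO, ho, wo, N, C, Do, Ho);
            y[yi] = best;
            arg[yi] = (double)best_i;
          }
  y.attr("dim") = IntegerVector::create(N, C, Do, Ho, Wo);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector dy, NumericVector argmax,
                            IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    dx[(R_xlen_t)argmax[i]] += dy[i];
  }
  dx.attr("dim") = xdim;
  return dx;
}
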