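// Low-level neural-network kernels.
//
// All image batches are R arrays with dim c(H, W, C, N) in column-major
// order; kernels are c(kh, kw, Cin, Cout).  Convolutions are organized as
// plane sweeps: for each (kh, kw, ci, co) the kernel tap contributes a
// scaled, shifted copy of the input plane to the output plane, giving long
// contiguous inner loops over the image rows.  Loops run in a fixed order
// with no threading so results are bitwise reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline int cdiv_ceil(int a, int b) { return a >= 0 ? (a + b - 1) / b : -((-a) / b); }
static inline int cdiv_floor(int a, int b) { return a >= 0 ? a / b : -cdiv_ceil(-a, b); }

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector k,
                             NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = k.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int KH = kd[0], KW = kd[1], Co = kd[3];
  const int Ho = (H + 2 * pad - KH) / stride + 1;
  const int Wo = (W + 2 * pad - KW) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  const double *px = x.begin(), *pk = k.begin(), *pb = bias.begin();
  double *py = y.begin();
  const R_xlen_t xplane = static_cast<R_xlen_t>(H) * W;
  const R_xlen_t yplane = static_cast<R_xlen_t>(Ho) * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double *yp = py + yplane * (co + static_cast<R_xlen_t>(Co) * n);
      const double b = pb[co];
      for (R_xlen_t i = 0; i < yplane; ++i) yp[i] = b;
      for (int ci = 0; ci < Ci; ++ci) {
        const double *xp = px + xplane * (ci + static_cast<R_xlen_t>(Ci) * n);
        for (int kw = 0; kw < KW; ++kw)
          for (int kh = 0; kh < KH; ++kh) {
            const double wv = pk[kh + KH * (kw + KW * (ci + Ci * co))];
            if (wv == 0.0) continue;
            // valid output ranges so that 0 <= h0+ho*s < H etc.
            const int h0 = kh - pad, w0 = kw - pad;
            const int ho_lo = std::max(0, cdiv_ceil(-h0, stride));
            const int ho_hi = std::min(Ho - 1, cdiv_floor(H - 1 - h0, stride));
            const int wo_lo = std::max(0, cdiv_ceil(-w0, stride));
            const int wo_hi = std::min(Wo - 1, cdiv_floor(W - 1 - w0, stride));
            for (int wo = wo_lo; wo <= wo_hi; ++wo) {
              const double *__restrict__ xc = xp + static_cast<R_xlen_t>(H) * (w0 + wo * stride) + h0;
              double *__restrict__ yc = yp + static_cast<R_xlen_t>(Ho) * wo;
              if (stride == 1) {
                for (int ho = ho_lo; ho <= ho_hi; ++ho)
                  yc[ho] += wv * xc[ho];
              } else {
                for (int ho = ho_lo; ho <= ho_hi; ++ho)
                  yc[ho] += wv * xc[static_cast<R_xlen_t>(ho) * stride];
              }
            }
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector k, NumericVector gy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = k.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int KH = kd[0], KW = kd[1], Co = kd[3];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx(x.size()), gk(k.size()), gb(Co);
  gx.attr("dim") = xd;
  gk.attr("dim") = kd;
  const double *px = x.begin(), *pk = k.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgk = gk.begin(), *pgb = gb.begin();
  const R_xlen_t xplane = static_cast<R_xlen_t>(H) * W;
  const R_xlen_t yplane = static_cast<R_xlen_t>(Ho) * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double *gp = pg + yplane * (co + static_cast<R_xlen_t>(Co) * n);
      double acc_b = 0.0;
      for (R_xlen_t i = 0; i < yplane; ++i) acc_b += gp[i];
      pgb[co] += acc_b;
      for (int ci = 0; ci < Ci; ++ci) {
        const double *xp = px + xplane * (ci + static_cast<R_xlen_t>(Ci) * n);
        double *gxp = pgx + xplane * (ci + static_cast<R_xlen_t>(Ci) * n);
        for (int kw = 0; kw < KW; ++kw)
          for (int kh = 0; kh < KH; ++kh) {
            const int ki = kh + KH * (kw + KW * (ci + Ci * co));
            const double wv = pk[ki];
            const int h0 = kh - pad, w0 = kw - pad;
            const int ho_lo = std::max(0, cdiv_ceil(-h0, stride));
            const int ho_hi = std::min(Ho - 1, cdiv_floor(H - 1 - h0, stride));
            const int wo_lo = std::max(0, cdiv_ceil(-w0, stride));
            const int wo_hi = std::min(Wo - 1, cdiv_floor(W - 1 - w0, stride));
            double acc_w = 0.0;
            for (int wo = wo_lo; wo <= wo_hi; ++wo) {
              const double *__restrict__ xc = xp + static_cast<R_xlen_t>(H) * (w0 + wo * stride) + h0;
              double *__restrict__ gxc = gxp + static_cast<R_xlen_t>(H) * (w0 + wo * stride) + h0;
              const double *__restrict__ gc = gp + static_cast<R_xlen_t>(Ho) * wo;
              if (stride == 1) {
                for (int ho = ho_lo; ho <= ho_hi; ++ho) {
                  const double g = gc[ho];
                  acc_w += xc[ho] * g;
                  gxc[ho] += wv * g;
                }
              } else {
                for (int ho = ho_lo; ho <= ho_hi; ++ho) {
                  const double g = gc[ho];
                  const R_xlen_t off = static_cast<R_xlen_t>(ho) * stride;
                  acc_w += xc[off] * g;
                  gxc[off] += wv * g;
                }
              }
            }
            pgk[ki] += acc_w;
          }
      }
    }
  return List::create(_["gx"] = gx, _["gk"] = gk, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(static_cast<R_xlen_t>(4) * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  const R_xlen_t planes = static_cast<R_xlen_t>(C) * N;
  for (R_xlen_t p = 0; p < planes; ++p) {
    const double *xp = px + static_cast<R_xlen_t>(H) * W * p;
    double *yp = py + static_cast<R_xlen_t>(4) * H * W * p;
    for (int w = 0; w < W; ++w) {
      const double *__restrict__ xc = xp + static_cast<R_xlen_t>(H) * w;
      double *y1 = yp + static_cast<R_xlen_t>(2 * H) * (2 * w);
      double *y2 = yp + static_cast<R_xlen_t>(2 * H) * (2 * w + 1);
      for (int h = 0; h < H; ++h) {
        const double v = xc[h];
        y1[2 * h] = v; y1[2 * h + 1] = v;
        y2[2 * h] = v; y2[2 * h + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  const int H2 = gd[0], W2 = gd[1], C = gd[2], N = gd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pg = gy.begin();
  double *px = gx.begin();
  const R_xlen_t planes = static_cast<R_xlen_t>(C) * N;
  for (R_xlen_t p = 0; p < planes; ++p) {
    double *xp = px + static_cast<R_xlen_t>(H) * W * p;
    const double *gp = pg + static_cast<R_xlen_t>(H2) * W2 * p;
    for (int w = 0; w < W; ++w) {
      double *xc = xp + static_cast<R_xlen_t>(H) * w;
      const double *g1 = gp + static_cast<R_xlen_t>(H2) * (2 * w);
      const double *g2 = gp + static_cast<R_xlen_t>(H2) * (2 * w + 1);
      for (int h = 0; h < H; ++h)
        xc[h] = g1[2 * h] + g1[2 * h + 1] + g2[2 * h] + g2[2 * h + 1];
    }
  }
  return gx;
}
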