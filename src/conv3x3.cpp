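#include <Rcpp.h>
using namespace Rcpp;

// 3x3 same-padding convolution kernels for the reduced residual CNN.
// Tensor layout is column-major (H, W, C, B): index = h + H*(w + W*(c + C*b)).
// Kernel layout is (3, 3, Cin, Cout): index = kh + 3*(kw + 3*(ci + Cin*co)).

static inline int idx4(int h, int w, int c, int b, int H, int W, int C) {
  return h + H * (w + W * (c + C * b));
}

// [[Rcpp::export]]
NumericVector cnn_conv3x3_fwd(NumericVector x, IntegerVector dims,
                              NumericVector k, NumericVector bias) {
  const int H = dims[0], W = dims[1], Cin = dims[2], B = dims[3];
  const int Cout = bias.size();
  NumericVector y(((R_xlen_t)H) * W * Cout * B);
  const double *px = x.begin(), *pk = k.begin();
  double *py = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      double *yb = py + idx4(0, 0, co, b, H, W, Cout);
      const double bi = bias[co];
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) yb[h + H * w] = bi;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xb = px + idx4(0, 0, ci, b, H, W, Cin);
        const double *kk = pk + 9 * (ci + Cin * co);
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            const double kv = kk[(dh + 1) + 3 * (dw + 1)];
            if (kv == 0.0) continue;
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            for (int w = w0; w < w1; ++w) {
              const double *xcol = xb + H * (w + dw) + dh;
              double *ycol = yb + H * w;
              for (int h = h0; h < h1; ++h) ycol[h] += kv * xcol[h];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return y;
}

// [[Rcpp::export]]
List cnn_conv3x3_bwd(NumericVector x, NumericVector dy, IntegerVector dims,
                     NumericVector k, int Cout) {
  const int H = dims[0], W = dims[1], Cin = dims[2], B = dims[3];
  NumericVector dx(((R_xlen_t)H) * W * Cin * B);
  NumericVector dk(9 * Cin * Cout);
  NumericVector db(Cout);
  const double *px = x.begin(), *pdy = dy.begin(), *pk = k.begin();
  double *pdx = dx.begin(), *pdk = dk.begin(), *pdb = db.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      const double *dyb = pdy + idx4(0, 0, co, b, H, W, Cout);
      double s = 0.0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) s += dyb[h + H * w];
      pdb[co] += s;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xb = px + idx4(0, 0, ci, b, H, W, Cin);
        double *dxb = pdx + idx4(0, 0, ci, b, H, W, Cin);
        const double *kk = pk + 9 * (ci + Cin * co);
        double *dkk = pdk + 9 * (ci + Cin * co);
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            const double kv = kk[(dh + 1) + 3 * (dw + 1)];
            double acc = 0.0;
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            for (int w = w0; w < w1; ++w) {
              const double *xcol = xb + H * (w + dw) + dh;
              double *dxcol = dxb + H * (w + dw) + dh;
              const double *dycol = dyb + H * w;
              for (int h = h0; h < h1; ++h) {
                acc += xcol[h] * dycol[h];
                dxcol[h] += kv * dycol[h];
              }
            }
            dkk[(dh + 1) + 3 * (dw + 1)] += acc;
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  dk.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  return List::create(_["dx"] = dx, _["dk"] = dk, _["db"] = db);
}

// 2x2 mean pooling (stride 2). H and W must be even.
// [[Rcpp::export]]
NumericVector cnn_pool2_fwd(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(((R_xlen_t)Ho) * Wo * C * B);
  const double *px = x.begin();
  double *py = y.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const double *xp = px + ((R_xlen_t)H) * W * cb;
    double *yp = py + ((R_xlen_t)Ho) * Wo * cb;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        yp[h + Ho * w] = 0.25 * (xp[2 * h + H * (2 * w)] +
                                 xp[2 * h + 1 + H * (2 * w)] +
                                 xp[2 * h + H * (2 * w + 1)] +
                                 xp[2 * h + 1 + H * (2 * w + 1)]);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return y;
}

// [[Rcpp::export]]
NumericVector cnn_pool2_bwd(NumericVector dy, IntegerVector dims_in) {
  const int H = dims_in[0], W = dims_in[1], C = dims_in[2], B = dims_in[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx(((R_xlen_t)H) * W * C * B);
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const double *dyp = pdy + ((R_xlen_t)Ho) * Wo * cb;
    double *dxp = pdx + ((R_xlen_t)H) * W * cb;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double g = 0.25 * dyp[h + Ho * w];
        dxp[2 * h + H * (2 * w)] = g;
        dxp[2 * h + 1 + H * (2 * w)] = g;
        dxp[2 * h + H * (2 * w + 1)] = g;
        dxp[2 * h + 1 + H * (2 * w + 1)] = g;
      }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return dx;
}
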