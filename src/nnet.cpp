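// Minimal 2D convolutional kernels used by the organ segmentation networks.
// Tensors are R arrays in column-major order with dim (H, W, C, N).
// Convolutions are implemented as im2col + GEMM through Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector makeArr4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector makeIntArr4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::mat im2col(const double* x, int H, int W, int C, int k) {
  // rows: kh + k*kw + k*k*ci ; cols: h + H*w ; zero padding (k-1)/2
  const int pad = (k - 1) / 2;
  arma::mat col(k * k * C, (size_t)H * W, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          if (ws < 0 || ws >= W) continue;
          const double* src = xc + (size_t)ws * H;
          double* dst = col.memptr() + (size_t)r + col.n_rows * ((size_t)H * w);
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            if (hs < 0 || hs >= H) continue;
            dst[(size_t)h * col.n_rows] = src[hs];
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_add(const arma::mat& col, double* dx, int H, int W,
                              int C, int k) {
  const int pad = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * kw + k * k * ci;
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          if (ws < 0 || ws >= W) continue;
          double* dst = xc + (size_t)ws * H;
          const double* src = col.memptr() + (size_t)r + col.n_rows * ((size_t)H * w);
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            if (hs < 0 || hs >= H) continue;
            dst[hs] += src[(size_t)h * col.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  NumericVector out = makeArr4(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
                     false, true);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * plane * C, H, W, C, k);
    arma::mat y = Wm.t() * col;  // Cout x HW
    double* o = out.begin() + (size_t)n * plane * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      for (size_t p = 0; p < plane; ++p) o[(size_t)co * plane + p] = y(co, p) + bias;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  NumericVector dx = makeArr4(H, W, C, N);
  NumericVector dw = makeArr4(k, k, Cin, Cout);
  NumericVector db(Cout);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
                     false, true);
  arma::mat dWm((size_t)k * k * Cin, Cout, arma::fill::zeros);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * plane * C, H, W, C, k);
    arma::mat dym(Cout, plane);
    const double* dyp = dy.begin() + (size_t)n * plane * Cout;
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      for (size_t p = 0; p < plane; ++p) {
        const double v = dyp[(size_t)co * plane + p];
        dym(co, p) = v;
        s += v;
      }
      db[co] += s;
    }
    dWm += col * dym.t();
    arma::mat dcol = Wm * dym;  // (k*k*Cin) x HW
    col2im_add(dcol, dx.begin() + (size_t)n * plane * C, H, W, C, k);
  }
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = makeArr4(Ho, Wo, C, N);
  IntegerVector idx = makeIntArr4(Ho, Wo, C, N);
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * plane;
    double* yp = y.begin() + cn * oplane;
    int* ip = idx.begin() + cn * oplane;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho, w = 2 * wo;
        double best = xp[h + (size_t)H * w];
        int bi = 0;
        const double cands[3] = {xp[h + 1 + (size_t)H * w],
                                 xp[h + (size_t)H * (w + 1)],
                                 xp[h + 1 + (size_t)H * (w + 1)]};
        for (int j = 0; j < 3; ++j)
          if (cands[j] > best) { best = cands[j]; bi = j + 1; }
        yp[ho + (size_t)Ho * wo] = best;
        ip[ho + (size_t)Ho * wo] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx = makeArr4(H, W, C, N);
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* dyp = dy.begin() + cn * oplane;
    const int* ip = idx.begin() + cn * oplane;
    double* dxp = dx.begin() + cn * plane;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int bi = ip[ho + (size_t)Ho * wo];
        const int h = 2 * ho + (bi == 1 || bi == 3);
        const int w = 2 * wo + (bi >= 2);
        dxp[h + (size_t)H * w] += dyp[ho + (size_t)Ho * wo];
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = makeArr4(Ho, Wo, C, N);
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + cn * plane;
    double* yp = y.begin() + cn * oplane;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        yp[ho + (size_t)Ho * wo] = xp[(ho / 2) + (size_t)H * (wo / 2)];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx = makeArr4(H, W, C, N);
  const size_t plane = (size_t)H * W, oplane = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* dyp = dy.begin() + cn * oplane;
    double* dxp = dx.begin() + cn * plane;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        dxp[(ho / 2) + (size_t)H * (wo / 2)] += dyp[ho + (size_t)Ho * wo];
  }
  return dx;
}
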