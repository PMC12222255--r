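// Low-level numerical kernels: 2D convolution (same padding) with exact
// gradients via im2col/col2im + GEMM, 2x2 max pooling, bilinear x2
// up-sampling with its adjoint, and separable 3D filtering with replicate
// edge padding. Activation tensors are column-major R arrays laid out
// (H, W, C, B); kernels are (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
using namespace Rcpp;

static void get_dims(const NumericVector &x, int *d, int n) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != n) stop("unexpected array rank");
  for (int i = 0; i < n; ++i) d[i] = dim[i];
}

// im2col for one sample: rows indexed (ki, kj, ci), cols indexed (i, j)
static void im2col(const double *x, int H, int W, int Ci, int kh, int kw,
                   int pad, arma::mat &M) {
  for (int ci = 0; ci < Ci; ++ci) {
    const double *xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        double *Mr = M.memptr() + r; // stride M.n_rows per column
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          bool jok = jj >= 0 && jj < W;
          for (int i = 0; i < H; ++i) {
            int ii = i + ki - pad;
            double v = 0.0;
            if (jok && ii >= 0 && ii < H) v = xc[ii + (size_t)H * jj];
            Mr[(size_t)M.n_rows * (i + (size_t)H * j)] = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat &M, int H, int W, int Ci, int kh,
                       int kw, int pad, double *dx) {
  for (int ci = 0; ci < Ci; ++ci) {
    double *xc = dx + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        const double *Mr = M.memptr() + r;
        for (int j = 0; j < W; ++j) {
          int jj = j + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int ii = i + ki - pad;
            if (ii < 0 || ii >= H) continue;
            xc[ii + (size_t)H * jj] +=
              Mr[(size_t)M.n_rows * (i + (size_t)H * j)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias) {
  int dx_[4], dw_[4];
  get_dims(x, dx_, 4);
  get_dims(w, dw_, 4);
  int H = dx_[0], W = dx_[1], Ci = dx_[2], B = dx_[3];
  int kh = dw_[0], kw = dw_[1], Co = dw_[3];
  if (dw_[2] != Ci) stop("channel mismatch");
  int pad = kh / 2;
  int K = kh * kw * Ci, HW = H * W;
  arma::mat Wm(const_cast<double *>(w.begin()), K, Co, false, true);
  NumericVector y((R_xlen_t)((size_t)HW * Co * B));
  arma::mat M(K, HW);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)HW * Ci * b, H, W, Ci, kh, kw, pad, M);
    arma::mat Y = Wm.t() * M; // Co x HW
    double *yb = y.begin() + (size_t)HW * Co * b;
    for (int co = 0; co < Co; ++co) {
      double bc = bias[co];
      const double *Yr = Y.memptr() + co;
      double *yc = yb + (size_t)HW * co;
      for (int p = 0; p < HW; ++p) yc[p] = Yr[(size_t)Co * p] + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  int dx_[4], dw_[4];
  get_dims(x, dx_, 4);
  get_dims(w, dw_, 4);
  int H = dx_[0], W = dx_[1], Ci = dx_[2], B = dx_[3];
  int kh = dw_[0], kw = dw_[1], Co = dw_[3];
  int pad = kh / 2;
  int K = kh * kw * Ci, HW = H * W;
  arma::mat Wm(const_cast<double *>(w.begin()), K, Co, false, true);
  NumericVector dxv((size_t)HW * Ci * B);
  NumericVector dwv((size_t)K * Co);
  NumericVector dbv(Co);
  arma::mat dW(dwv.begin(), K, Co, false, true);
  arma::mat M(K, HW);
  arma::mat dY(Co, HW);
  for (int b = 0; b < B; ++b) {
    const double *dyb = dy.begin() + (size_t)HW * Co * b;
    for (int co = 0; co < Co; ++co) {
      const double *dyc = dyb + (size_t)HW * co;
      double s = 0.0;
      double *dYr = dY.memptr() + co;
      for (int p = 0; p < HW; ++p) {
        dYr[(size_t)Co * p] = dyc[p];
        s += dyc[p];
      }
      dbv[co] += s;
    }
    im2col(x.begin() + (size_t)HW * Ci * b, H, W, Ci, kh, kw, pad, M);
    dW += M * dY.t();
    arma::mat dXcols = Wm * dY; // K x HW
    col2im_add(dXcols, H, W, Ci, kh, kw, pad,
               dxv.begin() + (size_t)HW * Ci * b);
  }
  dxv.attr("dim") = IntegerVector::create(H, W, Ci, B);
  dwv.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  int d[4];
  get_dims(x, d, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3];
  if (H % 2 || W % 2) stop("max pooling needs even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  size_t nout = (size_t)Ho * Wo * C * B;
  NumericVector y(nout);
  IntegerVector arg(nout);
  const double *xp = x.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)H * W * (c + (size_t)C * b);
      size_t offo = (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300;
          size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t ii = off + (2 * i + di) + (size_t)H * (2 * j + dj);
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          y[offo + i + (size_t)Ho * j] = best;
          arg[offo + i + (size_t)Ho * j] = (int)bi;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector argmax,
                               IntegerVector in_dim) {
  size_t n = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(n);
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[argmax[k]] += dy[k];
  dx.attr("dim") = in_dim;
  return dx;
}

// bilinear x2 axis weights: output o samples input at o/2 - 0.25 (clamped)
static void up2_weights(int H, std::vector<int> &i0, std::vector<int> &i1,
                        std::vector<double> &w0) {
  int Ho = 2 * H;
  i0.resize(Ho); i1.resize(Ho); w0.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = 0.5 * o - 0.25;
    int lo = (int)std::floor(src);
    double f = src - lo;
    int a = std::min(std::max(lo, 0), H - 1);
    int b = std::min(std::max(lo + 1, 0), H - 1);
    i0[o] = a; i1[o] = b; w0[o] = 1.0 - f;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x) {
  int d[4];
  get_dims(x, d, 4);
  int H = d[0], W = d[1], C = d[2], B = d[3], Ho = 2 * H, Wo = 2 * W;
  std::vector<int> ri0, ri1, ci0, ci1;
  std::vector<double> rw, cw;
  up2_weights(H, ri0, ri1, rw);
  up2_weights(W, ci0, ci1, cw);
  NumericVector y((size_t)Ho * Wo * C * B);
  const double *xp = x.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (size_t)H * W * (c + (size_t)C * b);
      double *yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int j = 0; j < Wo; ++j) {
        int j0 = ci0[j], j1 = ci1[j];
        double wj = cw[j];
        for (int i = 0; i < Ho; ++i) {
          double wi = rw[i];
          double v = wi * wj * xc[ri0[i] + (size_t)H * j0] +
                     wi * (1 - wj) * xc[ri0[i] + (size_t)H * j1] +
                     (1 - wi) * wj * xc[ri1[i] + (size_t)H * j0] +
                     (1 - wi) * (1 - wj) * xc[ri1[i] + (size_t)H * j1];
          yc[i + (size_t)Ho * j] = v;
        }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dy, IntegerVector in_dim) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], B = in_dim[3];
  int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> ri0, ri1, ci0, ci1;
  std::vector<double> rw, cw;
  up2_weights(H, ri0, ri1, rw);
  up2_weights(W, ci0, ci1, cw);
  NumericVector dx((size_t)H * W * C * B);
  const double *dyp = dy.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double *xc = dx.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double *yc = dyp + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int j = 0; j < Wo; ++j) {
        int j0 = ci0[j], j1 = ci1[j];
        double wj = cw[j];
        for (int i = 0; i < Ho; ++i) {
          double wi = rw[i];
          double g = yc[i + (size_t)Ho * j];
          xc[ri0[i] + (size_t)H * j0] += wi * wj * g;
          xc[ri0[i] + (size_t)H * j1] += wi * (1 - wj) * g;
          xc[ri1[i] + (size_t)H * j0] += (1 - wi) * wj * g;
          xc[ri1[i] + (size_t)H * j1] += (1 - wi) * (1 - wj) * g;
        }
      }
    }
  dx.attr("dim") = in_dim;
  return dx;
}

// [[Rcpp::export]]
NumericVector sep_conv3_cpp(NumericVector vol, NumericVector kernel,
                            int axis) {
  int d[3];
  get_dims(vol, d, 3);
  int r = (kernel.size() - 1) / 2;
  NumericVector out((size_t)d[0] * d[1] * d[2]);
  const double *v = vol.begin();
  double *o = out.begin();
  int n = d[axis - 1];
  // iterate over all lines along `axis`
  size_t stride = 1;
  for (int a = 0; a < axis - 1; ++a) stride *= d[a];
  size_t nlines = ((size_t)d[0] * d[1] * d[2]) / n;
  for (size_t line = 0; line < nlines; ++line) {
    size_t li = line;
    size_t base;
    int coords[3];
    for (int a = 0; a < 3; ++a) {
      if (a == axis - 1) { coords[a] = 0; continue; }
      coords[a] = (int)(li % d[a]);
      li /= d[a];
    }
    base = coords[0] + (size_t)d[0] * (coords[1] + (size_t)d[1] * coords[2]);
    for (int i = 0; i < n; ++i) {
      double acc = 0;
      for (int k = -r; k <= r; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0;
        if (ii >= n) ii = n - 1;
        acc += kernel[k + r] * v[base + (size_t)ii * stride];
      }
      o[base + (size_t)i * stride] = acc;
    }
  }
  out.attr("dim") = IntegerVector::create(d[0], d[1], d[2]);
  return out;
}
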