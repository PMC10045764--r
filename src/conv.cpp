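// Zero-padded "same" 2-D convolution layers via im2col + GEMM.
//
// Array conventions (all column-major, matching R):
//   activations : H x W x C x N  (H fastest)
//   weights     : (k*k*Cin) x Cout matrix; row index of a tap is
//                 di + k*dj + k*k*c  with di/dj the 0-based kernel row/col
//                 offset and c the input channel.
// With those layouts the per-sample forward pass is a single GEMM:
//   Y (HW x Cout) = colT (HW x k*k*Cin) * W.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Build transposed im2col matrix for one sample: (H*W) x (k*k*C).
static void im2col_t(const double* x, const int H, const int W, const int C,
                     const int k, mat& colT) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + HW * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* dst = colT.colptr(di + k * dj + k * k * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          double* d = dst + (size_t)H * j;
          if (sj < 0 || sj >= W) {
            std::fill(d, d + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * sj + (di - p);
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            d[i] = (si < 0 || si >= H) ? 0.0 : src[i];
          }
        }
      }
    }
  }
}

// Scatter-add of the transposed column gradient back onto the input image.
static void col2im_t(const mat& gcolT, const int H, const int W, const int C,
                     const int k, double* gx) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* gxc = gx + HW * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* src = gcolT.colptr(di + k * dj + k * k * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const double* s = src + (size_t)H * j;
          double* d = gxc + (size_t)H * sj + (di - p);
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si >= 0 && si < H) d[i] += s[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
Rcpp::NumericVector conv2d_forward(const Rcpp::NumericVector& x,
                                   const Rcpp::NumericMatrix& w,
                                   const Rcpp::Nullable<Rcpp::NumericVector>& bias,
                                   const int kernel) {
  const Rcpp::IntegerVector dims(x.attr("dim"));
  if (dims.size() != 4) Rcpp::stop("input must be a 4-D array (H, W, C, N)");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int k = kernel;
  if (w.nrow() != k * k * C)
    Rcpp::stop("weight rows (%d) do not match k*k*Cin (%d)", w.nrow(), k * k * C);
  const int Cout = w.ncol();
  const size_t HW = (size_t)H * W;

  const mat wm(const_cast<double*>(w.begin()), w.nrow(), Cout, false, true);
  Rcpp::NumericVector out(Rcpp::no_init((R_xlen_t)HW * Cout * N));
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, Cout, N);
  mat colT(HW, (size_t)k * k * C);

  rowvec bv;
  const bool has_bias = bias.isNotNull();
  if (has_bias) {
    Rcpp::NumericVector b(bias);
    if (b.size() != Cout) Rcpp::stop("bias length must equal Cout");
    bv = rowvec(b.begin(), Cout);
  }

  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + HW * C * n, H, W, C, k, colT);
    mat y(out.begin() + HW * Cout * n, HW, Cout, false, true);
    y = colT * wm;
    if (has_bias) y.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
Rcpp::List conv2d_backward(const Rcpp::NumericVector& x,
                           const Rcpp::NumericMatrix& w,
                           const Rcpp::NumericVector& gy,
                           const int kernel,
                           const bool need_gx,
                           const bool need_gb) {
  const Rcpp::IntegerVector dims(x.attr("dim"));
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int k = kernel;
  const int Cout = w.ncol();
  const size_t HW = (size_t)H * W;

  const mat wm(const_cast<double*>(w.begin()), w.nrow(), Cout, false, true);
  mat gw(w.nrow(), Cout, fill::zeros);
  vec gb(Cout, fill::zeros);
  Rcpp::NumericVector gx;
  if (need_gx) {
    gx = Rcpp::NumericVector((R_xlen_t)HW * C * N);  // zero-initialised
    gx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  }

  mat colT(HW, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + HW * C * n, H, W, C, k, colT);
    const mat gyn(const_cast<double*>(gy.begin()) + HW * Cout * n, HW, Cout,
                  false, true);
    gw += colT.t() * gyn;
    if (need_gb) gb += sum(gyn, 0).t();
    if (need_gx) {
      mat gcolT = gyn * wm.t();
      col2im_t(gcolT, H, W, C, k, gx.begin() + HW * C * n);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("gx") = need_gx ? (SEXP)gx : R_NilValue,
      Rcpp::Named("gw") = gw,
      Rcpp::Named("gb") = need_gb ? Rcpp::wrap(Rcpp::NumericVector(gb.begin(), gb.end()))
                                  : (SEXP)R_NilValue);
}
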