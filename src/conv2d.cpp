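// Stride-1, same-padding 2-D convolution (im2col + GEMM) used by the
// autodiff engine.  Array layout throughout the package: (H, W, C, N),
// column-major as stored by R; weights are (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill `col` ((Cin*kh*kw) x (H*W)) with the padded patches of sample n.
// Row index of (ci, kj, ki) is ci*kh*kw + kj*kh + ki.
static void im2col(const double *xs, int H, int W, int Ci,
                   int kh, int kw, arma::mat &col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  col.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    const double *xc = xs + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ci * kh * kw + kj * kh + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pw;
          if (sj < 0 || sj >= W) continue;
          const int lo = std::max(0, ph - ki);
          const int hi = std::min(H, H + ph - ki);
          const double *src = xc + (size_t)H * sj + (ki - ph);
          double *dst = col.colptr(0) + r; // advance by nrow per pixel
          const size_t nr = col.n_rows;
          for (int i = lo; i < hi; ++i)
            dst[((size_t)H * j + i) * nr] = src[i];
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector &w, int kh, int kw,
                               int Ci, int Co) {
  arma::mat Wm(Co, (size_t)Ci * kh * kw);
  const double *wp = w.begin();
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wm(co, ci * kh * kw + kj * kh + ki) =
              wp[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)Ci * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != Ci) stop("conv2d: input channels (%d) do not match kernel (%d)", Ci, wd[2]);
  if (kh % 2 == 0 || kw % 2 == 0) stop("conv2d: kernel size must be odd");

  arma::mat Wm = weight_matrix(w, kh, kw, Ci, Co);
  NumericVector y((size_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat col((size_t)Ci * kh * kw, (size_t)H * W);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, kh, kw, col);
    arma::mat out = Wm * col; // Co x (H*W)
    double *yp = y.begin() + (size_t)H * W * Co * n;
    for (int co = 0; co < Co; ++co) {
      const double bb = b[co];
      double *ys = yp + (size_t)H * W * co;
      for (size_t p = 0; p < (size_t)H * W; ++p) ys[p] = out(co, p) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;

  arma::mat Wm = weight_matrix(w, kh, kw, Ci, Co);
  arma::mat dW(Co, (size_t)Ci * kh * kw, arma::fill::zeros);
  arma::mat col((size_t)Ci * kh * kw, (size_t)H * W);

  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * Ci * N);
    dx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  }

  for (int n = 0; n < N; ++n) {
    // dy of sample n as Co x (H*W)
    arma::mat dyn(Co, (size_t)H * W);
    const double *dp = dy.begin() + (size_t)H * W * Co * n;
    for (int co = 0; co < Co; ++co)
      for (size_t p = 0; p < (size_t)H * W; ++p)
        dyn(co, p) = dp[(size_t)H * W * co + p];

    im2col(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, kh, kw, col);
    dW += dyn * col.t();

    if (need_dx) {
      arma::mat colg = Wm.t() * dyn; // (Ci*kh*kw) x (H*W): col2im scatter-add
      double *dxs = dx.begin() + (size_t)H * W * Ci * n;
      for (int ci = 0; ci < Ci; ++ci) {
        double *dxc = dxs + (size_t)H * W * ci;
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            const int r = ci * kh * kw + kj * kh + ki;
            for (int j = 0; j < W; ++j) {
              const int sj = j + kj - pw;
              if (sj < 0 || sj >= W) continue;
              for (int i = 0; i < H; ++i) {
                const int si = i + ki - ph;
                if (si < 0 || si >= H) continue;
                dxc[si + (size_t)H * sj] += colg(r, (size_t)H * j + i);
              }
            }
          }
        }
      }
    }
  }

  NumericVector dwv((size_t)kh * kw * Ci * Co);
  dwv.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  double *dwp = dwv.begin();
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dwp[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)Ci * co))] =
              dW(co, ci * kh * kw + kj * kh + ki);

  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dwv);
}
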