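// Minimal conv-net kernels: 3x3 same-padding convolution (fused ReLU) and
// 2x2 max pooling, forward and backward, via im2col + GEMM (Armadillo).
// Layouts:
//   feature maps: column-major arrays dim (H, W, C, N)
//   conv weights: matrix (9*Cin, Cout), patch row index = di + 3*dj + 9*c
// Loops are ordered so that the large buffers are written contiguously
// (im2col columns, transposed GEMM results); images are processed in groups
// so each GEMM is wide enough for BLAS without buffers growing past ~32 MB.
// The input gradient is computed R-side as a forward convolution with the
// 180-degree-rotated transposed kernel, so no col2im scatter is needed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void im2col3(const double* x, int H, int W, int C,
                           double* col) {
  // writes the (9*C) x (H*W) patch matrix of one image, column by column
  const size_t HW = (size_t)H * W;
  const int rows = 9 * C;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double* colp = col + ((size_t)i + (size_t)H * j) * rows;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * HW;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          const bool jok = jj >= 0 && jj < W;
          const double* xcol = xc + (size_t)H * jj;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            *colp++ = (jok && ii >= 0 && ii < H) ? xcol[ii] : 0.0;
          }
        }
      }
    }
  }
}

static inline int group_size(int C, size_t HW, int N) {
  size_t target = 4000000;  // ~32 MB of doubles
  size_t per = (size_t)9 * C * HW;
  int g = (int)std::max((size_t)1, target / std::max(per, (size_t)1));
  return std::min(g, N);
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                          bool relu = true) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol();
  if (w.nrow() != 9 * C) stop("weight/input channel mismatch");
  const size_t HW = (size_t)H * W;
  NumericVector out((R_xlen_t)HW * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  arma::mat wt = wm.t();
  int g = group_size(C, HW, N);
  arma::mat col(9 * C, HW * g);
  arma::mat y(Cout, HW * g);
  for (int n0 = 0; n0 < N; n0 += g) {
    int ng = std::min(g, N - n0);
    for (int k = 0; k < ng; ++k)
      im2col3(x.begin() + (size_t)(n0 + k) * HW * C, H, W, C,
              col.colptr(HW * k));
    if (ng == g) {
      y = wt * col;                                    // Cout x HW*g
    } else {
      col.resize(9 * C, HW * ng);
      y = wt * col;
    }
    for (int k = 0; k < ng; ++k) {
      double* op = out.begin() + (size_t)(n0 + k) * HW * Cout;
      for (size_t p = 0; p < HW; ++p) {
        const double* yp = y.colptr(HW * k + p);       // contiguous over co
        double* o = op + p;
        if (relu) {
          for (int co = 0; co < Cout; ++co) {
            double v = yp[co] + b[co];
            o[(size_t)co * HW] = v > 0 ? v : 0;
          }
        } else {
          for (int co = 0; co < Cout; ++co) o[(size_t)co * HW] = yp[co] + b[co];
        }
      }
    }
  }
  return out;
}

// Weight and bias gradients. dy must already be masked by the ReLU
// derivative (see relu_mask); the input gradient is obtained separately via
// conv3x3_fwd with the rotated kernel.
// [[Rcpp::export]]
List conv3x3_grad(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = w.ncol();
  const size_t HW = (size_t)H * W;
  NumericMatrix dw(w.nrow(), Cout);
  NumericVector db(Cout);
  arma::mat dwm(dw.begin(), w.nrow(), Cout, false);
  arma::vec dbv(db.begin(), Cout, false);
  int g = group_size(C, HW, N);
  arma::mat col(9 * C, HW * g);
  arma::mat dyT(HW * g, Cout);
  for (int n0 = 0; n0 < N; n0 += g) {
    int ng = std::min(g, N - n0);
    for (int k = 0; k < ng; ++k) {
      im2col3(x.begin() + (size_t)(n0 + k) * HW * C, H, W, C,
              col.colptr(HW * k));
      const double* dyp = dy.begin() + (size_t)(n0 + k) * HW * Cout;
      for (int co = 0; co < Cout; ++co) {
        double* t = dyT.colptr(co) + HW * k;
        const double* s = dyp + (size_t)co * HW;
        std::copy(s, s + HW, t);
      }
    }
    if (ng < g) {
      col.resize(9 * C, HW * ng);
      dyT.resize(HW * ng, Cout);
    }
    dwm += col * dyT;
    dbv += arma::sum(dyT, 0).t();
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// dy masked by the ReLU derivative of activation a (a > 0), out of place
// [[Rcpp::export]]
NumericVector relu_mask(NumericVector dy, NumericVector a) {
  NumericVector out(dy.size());
  out.attr("dim") = dy.attr("dim");
  const double* dp = dy.begin();
  const double* ap = a.begin();
  double* op = out.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) op[k] = ap[k] > 0 ? dp[k] : 0.0;
  return out;
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int H2 = H / 2, W2 = W / 2;
  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx(y.size());            // flat index into x of each max
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base_o = (size_t)H2 * W2 * (c + (size_t)C * n);
      size_t base_i = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          int bi = 2 * i, bj = 2 * j;
          double best = xp[bi + (size_t)H * bj];
          size_t barg = bi + (size_t)H * bj;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t q = (bi + di) + (size_t)H * (bj + dj);
              if (xp[q] > best) { best = xp[q]; barg = q; }
            }
          y[base_o + i + (size_t)H2 * j] = best;
          idx[base_o + i + (size_t)H2 * j] = (int)(base_i + barg);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < dy.size(); ++k) dx[idx[k]] += dy[k];
  return dx;
}
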