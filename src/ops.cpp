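// Low-level neural-net ops: im2col 2-D convolution and bilinear RoIAlign,
// forward and backward. Feature maps are arma::cube (H, W, C); conv weights
// are (Cout x k*k*Cin) matrices with row layout (ki, kj, c) fastest-first,
// matching the R-side packing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * stride + ki - pad;
            if (xi < 0 || xi >= H) continue;
            cols(r, (size_t)j * Ho + i) = x(xi, xj, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(arma::cube& dx, const arma::mat& dcols, int k,
                       int stride, int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * stride + ki - pad;
            if (xi < 0 || xi >= H) continue;
            dx(xi, xj, c) += dcols(r, (size_t)j * Ho + i);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube& x, const arma::mat& Wm,
                              const arma::vec& b, int k, int stride, int pad) {
  const int Ho = (int)((x.n_rows + 2 * pad - k) / stride) + 1;
  const int Wo = (int)((x.n_cols + 2 * pad - k) / stride) + 1;
  const int Cout = Wm.n_rows;
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat Y = Wm * cols;            // Cout x Ho*Wo
  Y.each_col() += b;
  arma::cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    y.slice(co) = arma::reshape(Y.row(co), Ho, Wo);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& x, const arma::mat& Wm,
                         const arma::cube& dy, int k, int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  arma::mat dY(Cout, (size_t)Ho * Wo);
  for (int co = 0; co < Cout; ++co) {
    dY.row(co) = arma::vectorise(dy.slice(co)).t();
  }
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat dW = dY * cols.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dcols = Wm.t() * dY;
  arma::cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  col2im_add(dx, dcols, k, stride, pad, Ho, Wo);
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

struct BilinW {
  int i0, j0;
  double w00, w01, w10, w11; // (i0,j0),(i0,j1),(i1,j0),(i1,j1)
};

static BilinW bilin(double y, double x, int H, int W) {
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  BilinW b;
  b.i0 = (int)std::floor(y); b.j0 = (int)std::floor(x);
  if (b.i0 > H - 2) b.i0 = H - 2 < 0 ? 0 : H - 2;
  if (b.j0 > W - 2) b.j0 = W - 2 < 0 ? 0 : W - 2;
  double fy = y - b.i0, fx = x - b.j0;
  if (H == 1) fy = 0; if (W == 1) fx = 0;
  b.w00 = (1 - fy) * (1 - fx); b.w01 = (1 - fy) * fx;
  b.w10 = fy * (1 - fx);       b.w11 = fy * fx;
  return b;
}

// rois: n x 4 (x1, y1, x2, y2) in feature-map coordinates (0-based, pixel
// centers at integers). One bilinear sample per output cell, at the cell
// center. Returns array (S, S, C, n).
// [[Rcpp::export]]
NumericVector cpp_roi_align_forward(const arma::cube& feat,
                                    const arma::mat& rois, int S) {
  const int H = feat.n_rows, W = feat.n_cols, C = feat.n_slices;
  const int n = rois.n_rows;
  NumericVector out((size_t)S * S * C * n);
  out.attr("dim") = IntegerVector::create(S, S, C, n);
  double* o = out.begin();
  for (int r = 0; r < n; ++r) {
    const double x1 = rois(r, 0), y1 = rois(r, 1);
    const double w = std::max(rois(r, 2) - x1, 1e-6);
    const double h = std::max(rois(r, 3) - y1, 1e-6);
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < S; ++j) {
        const double sx = x1 + (j + 0.5) * w / S;
        for (int i = 0; i < S; ++i) {
          const double sy = y1 + (i + 0.5) * h / S;
          BilinW bw = bilin(sy, sx, H, W);
          const int i1 = (H == 1) ? bw.i0 : bw.i0 + 1;
          const int j1 = (W == 1) ? bw.j0 : bw.j0 + 1;
          double v = bw.w00 * feat(bw.i0, bw.j0, c) + bw.w01 * feat(bw.i0, j1, c)
                   + bw.w10 * feat(i1, bw.j0, c)   + bw.w11 * feat(i1, j1, c);
          o[(size_t)r * S * S * C + (size_t)c * S * S + (size_t)j * S + i] = v;
        }
      }
    }
  }
  return out;
}

// dout: array (S, S, C, n); returns dfeat cube (H, W, C)
// [[Rcpp::export]]
arma::cube cpp_roi_align_backward(int H, int W, int C, const arma::mat& rois,
                                  int S, const NumericVector& dout) {
  const int n = rois.n_rows;
  arma::cube dfeat(H, W, C, arma::fill::zeros);
  const double* d = dout.begin();
  for (int r = 0; r < n; ++r) {
    const double x1 = rois(r, 0), y1 = rois(r, 1);
    const double w = std::max(rois(r, 2) - x1, 1e-6);
    const double h = std::max(rois(r, 3) - y1, 1e-6);
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < S; ++j) {
        const double sx = x1 + (j + 0.5) * w / S;
        for (int i = 0; i < S; ++i) {
          const double sy = y1 + (i + 0.5) * h / S;
          BilinW bw = bilin(sy, sx, H, W);
          const int i1 = (H == 1) ? bw.i0 : bw.i0 + 1;
          const int j1 = (W == 1) ? bw.j0 : bw.j0 + 1;
          const double g = d[(size_t)r * S * S * C + (size_t)c * S * S + (size_t)j * S + i];
          dfeat(bw.i0, bw.j0, c) += bw.w00 * g;
          dfeat(bw.i0, j1, c)    += bw.w01 * g;
          dfeat(i1, bw.j0, c)    += bw.w10 * g;
          dfeat(i1, j1, c)       += bw.w11 * g;
        }
      }
    }
  }
  return dfeat;
}

// IoU matrix between two box sets (n x 4, m x 4), corner convention.
// [[Rcpp::export]]
arma::mat cpp_iou_matrix(const arma::mat& A, const arma::mat& B) {
  const int n = A.n_rows, m = B.n_rows;
  arma::mat M(n, m, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const double ax1 = A(i,0), ay1 = A(i,1), ax2 = A(i,2), ay2 = A(i,3);
    const double aa = (ax2 - ax1) * (ay2 - ay1);
    for (int j = 0; j < m; ++j) {
      const double ix = std::min(ax2, B(j,2)) - std::max(ax1, B(j,0));
      if (ix <= 0) continue;
      const double iy = std::min(ay2, B(j,3)) - std::max(ay1, B(j,1));
      if (iy <= 0) continue;
      const double ab = (B(j,2) - B(j,0)) * (B(j,3) - B(j,1));
      const double un = aa + ab - ix * iy;
      if (un > 0) M(i, j) = ix * iy / un;
    }
  }
  return M;
}
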