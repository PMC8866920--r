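// 2-D convolution primitives for the slice segmenter.
// Layout conventions (column-major, matching R arrays):
//   feature map: cube H x W x C
//   weights:     matrix (kh*kw*Cin) x Cout, rows ordered (di, dj, ci)
//                i.e. exactly dim(array) <- c(kh*kw*Cin, Cout) of an
//                R array with dim c(kh, kw, Cin, Cout).
// Padding is zero-padding; output size floor((H + 2p - kh)/s) + 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  mat out(Ho * Wo, kh * kw * C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const mat& xs = x.slice(ci);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int q = di + kh * (dj + kw * ci);
        double* col = out.colptr(q);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + di;
            if (i < 0 || i >= H) continue;
            col[io + Ho * jo] = xs(i, j);
          }
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  cube x(H, W, C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    mat& xs = x.slice(ci);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int q = di + kh * (dj + kw * ci);
        const double* col = cols.colptr(q);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + di;
            if (i < 0 || i >= H) continue;
            xs(i, j) += col[io + Ho * jo];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw,
                          int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = w.n_cols;
  mat y = im2col(x, kh, kw, stride, pad) * w;  // (Ho*Wo) x Cout
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, int kh, int kw,
                          int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = w.n_cols;
  mat dyMat(const_cast<double*>(dy.memptr()),
            dy.n_rows * dy.n_cols, Cout, false, true);
  mat cols = im2col(x, kh, kw, stride, pad);
  mat dw = cols.t() * dyMat;
  vec db = sum(dyMat, 0).t();
  mat dcols = dyMat * w.t();
  cube dx = col2im(dcols, H, W, C, kh, kw, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// Voxel-count volumetry kernel: counts voxels equal to each class label.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_label_counts(const Rcpp::IntegerVector& labels,
                                     int n_classes) {
  Rcpp::NumericVector counts(n_classes + 1);  // classes 0..n_classes
  const int n = labels.size();
  for (int i = 0; i < n; ++i) {
    const int v = labels[i];
    if (v >= 0 && v <= n_classes) counts[v] += 1.0;
  }
  return counts;
}
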