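// Compiled kernels for the convolutional network: im2col/GEMM convolution
// with its adjoint, max/average pooling, and bilinear resizing.
//
// Feature maps are arma::cube with layout (rows, cols, channels), matching
// R arrays of dim c(H, W, C).  Convolution weights arrive flattened from an
// R array of dim c(kh, kw, Cin, Cout): column-major, so the GEMM weight
// matrix has kh*kw*Cin rows (kr fastest, then kc, then cin) and Cout columns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int ho, int wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(ho * wo, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; c++) {
    for (int kc = 0; kc < kw; kc++) {
      for (int kr = 0; kr < kh; kr++) {
        const int j = kr + kh * kc + kh * kw * c;
        for (int oc = 0; oc < wo; oc++) {
          const int ic = oc * stride + kc - pad;
          if (ic < 0 || ic >= W) continue;
          for (int orr = 0; orr < ho; orr++) {
            const int ir = orr * stride + kr - pad;
            if (ir < 0 || ir >= H) continue;
            col(orr + ho * oc, j) = x(ir, ic, c);
          }
        }
      }
    }
  }
  return col;
}

static void col2im(const mat& col, cube& gx, int kh, int kw, int stride,
                   int pad, int ho, int wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; c++) {
    for (int kc = 0; kc < kw; kc++) {
      for (int kr = 0; kr < kh; kr++) {
        const int j = kr + kh * kc + kh * kw * c;
        for (int oc = 0; oc < wo; oc++) {
          const int ic = oc * stride + kc - pad;
          if (ic < 0 || ic >= W) continue;
          for (int orr = 0; orr < ho; orr++) {
            const int ir = orr * stride + kr - pad;
            if (ir < 0 || ir >= H) continue;
            gx(ir, ic, c) += col(orr + ho * oc, j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw, int stride,
                      int pad) {
  const int ho = (int)(x.n_rows + 2 * pad - kh) / stride + 1;
  const int wo = (int)(x.n_cols + 2 * pad - kw) / stride + 1;
  const int cout = w.n_cols;
  mat col = im2col(x, kh, kw, stride, pad, ho, wo);
  mat out = col * w;               // (ho*wo) x cout
  out.each_row() += b.t();
  return cube(out.memptr(), ho, wo, cout);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, int kh, int kw, int stride,
                      int pad) {
  const int ho = gy.n_rows, wo = gy.n_cols, cout = gy.n_slices;
  mat col = im2col(x, kh, kw, stride, pad, ho, wo);
  mat gy_mat(const_cast<double*>(gy.memptr()), ho * wo, cout, false, true);
  mat gw = col.t() * gy_mat;       // (kh*kw*cin) x cout
  vec gb = sum(gy_mat, 0).t();
  mat gcol = gy_mat * w.t();
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im(gcol, gx, kh, kw, stride, pad, ho, wo);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// Max pooling, window k x k, stride k, floor output size; argmax indices
// (0-based, linear into x) are returned for the adjoint pass.
// [[Rcpp::export(name = ".maxpool_fwd")]]
Rcpp::List maxpool_fwd(const arma::cube& x, int k) {
  const int ho = x.n_rows / k, wo = x.n_cols / k, C = x.n_slices;
  cube out(ho, wo, C);
  Rcpp::IntegerVector idx(ho * wo * C);
  const int HW = x.n_rows * x.n_cols;
  for (int c = 0; c < C; c++) {
    for (int oc = 0; oc < wo; oc++) {
      for (int orr = 0; orr < ho; orr++) {
        double best = -datum::inf; int bi = 0;
        for (int kc = 0; kc < k; kc++) {
          for (int kr = 0; kr < k; kr++) {
            const int ir = orr * k + kr, ic = oc * k + kc;
            const double v = x(ir, ic, c);
            if (v > best) { best = v; bi = ir + x.n_rows * ic + HW * c; }
          }
        }
        out(orr, oc, c) = best;
        idx[orr + ho * oc + ho * wo * c] = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
arma::cube maxpool_bwd(const arma::cube& gy, const Rcpp::IntegerVector& idx,
                       int H, int W, int C) {
  cube gx(H, W, C, fill::zeros);
  const double* g = gy.memptr();
  for (int i = 0; i < (int)gy.n_elem; i++) gx(idx[i]) += g[i];
  return gx;
}

// [[Rcpp::export(name = ".avgpool2_fwd")]]
arma::cube avgpool2_fwd(const arma::cube& x) {
  const int ho = x.n_rows / 2, wo = x.n_cols / 2, C = x.n_slices;
  cube out(ho, wo, C);
  for (int c = 0; c < C; c++)
    for (int oc = 0; oc < wo; oc++)
      for (int orr = 0; orr < ho; orr++)
        out(orr, oc, c) = 0.25 * (x(2 * orr, 2 * oc, c) +
                                  x(2 * orr + 1, 2 * oc, c) +
                                  x(2 * orr, 2 * oc + 1, c) +
                                  x(2 * orr + 1, 2 * oc + 1, c));
  return out;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
arma::cube avgpool2_bwd(const arma::cube& gy) {
  const int H = gy.n_rows * 2, W = gy.n_cols * 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (int c = 0; c < C; c++)
    for (int ic = 0; ic < W; ic++)
      for (int ir = 0; ir < H; ir++)
        gx(ir, ic, c) = 0.25 * gy(ir / 2, ic / 2, c);
  return gx;
}

// Bilinear resize, half-pixel-center convention (the align_corners = FALSE
// convention of the deep-learning frameworks); the adjoint scatters with the
// same interpolation weights.
static inline void lin_coef(int i, double scale, int n, int& i0, int& i1,
                            double& w1) {
  double s = (i + 0.5) * scale - 0.5;
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n - 1);
  w1 = s - i0;
}

// [[Rcpp::export(name = ".resize_bilinear_fwd")]]
arma::cube resize_bilinear_fwd(const arma::cube& x, int ho, int wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const double sh = (double)H / ho, sw = (double)W / wo;
  cube out(ho, wo, C);
  for (int oc = 0; oc < wo; oc++) {
    int c0, c1; double wc;
    lin_coef(oc, sw, W, c0, c1, wc);
    for (int orr = 0; orr < ho; orr++) {
      int r0, r1; double wr;
      lin_coef(orr, sh, H, r0, r1, wr);
      for (int c = 0; c < C; c++)
        out(orr, oc, c) =
            (1 - wr) * (1 - wc) * x(r0, c0, c) + wr * (1 - wc) * x(r1, c0, c) +
            (1 - wr) * wc * x(r0, c1, c) + wr * wc * x(r1, c1, c);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".resize_bilinear_bwd")]]
arma::cube resize_bilinear_bwd(const arma::cube& gy, int H, int W) {
  const int ho = gy.n_rows, wo = gy.n_cols, C = gy.n_slices;
  const double sh = (double)H / ho, sw = (double)W / wo;
  cube gx(H, W, C, fill::zeros);
  for (int oc = 0; oc < wo; oc++) {
    int c0, c1; double wc;
    lin_coef(oc, sw, W, c0, c1, wc);
    for (int orr = 0; orr < ho; orr++) {
      int r0, r1; double wr;
      lin_coef(orr, sh, H, r0, r1, wr);
      for (int c = 0; c < C; c++) {
        const double g = gy(orr, oc, c);
        gx(r0, c0, c) += (1 - wr) * (1 - wc) * g;
        gx(r1, c0, c) += wr * (1 - wc) * g;
        gx(r0, c1, c) += (1 - wr) * wc * g;
        gx(r1, c1, c) += wr * wc * g;
      }
    }
  }
  return gx;
}
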