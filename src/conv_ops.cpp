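// Core dense kernels for the four-path network: 3x3 same-padding convolution
// (im2col + GEMM) and 2x2 stride-2 max pooling, each with its backward pass.
// Weight layout: w is (C_out x 9*C_in); column index j = cin*9 + kr*3 + kc,
// kr/kc in {0,1,2} indexing the kernel row/column. Checkpoints persist this
// layout, so it must never change silently.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3x3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(9 * C, H * W, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int kr = 0; kr < 3; ++kr) {
      for (int kc = 0; kc < 3; ++kc) {
        const arma::uword row = c * 9 + kr * 3 + kc;
        // output pixel (i,j) reads x(i+kr-1, j+kc-1); zero outside
        const int di = kr - 1, dj = kc - 1;
        for (arma::uword j = 0; j < W; ++j) {
          const int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          double* colptr = cols.colptr(j * H);
          // rows i with 0 <= i+di < H
          const arma::uword i0 = (di < 0) ? 1u : 0u;
          const arma::uword i1 = (di > 0) ? H - 1 : H;
          const double* src = xs.colptr(js);
          for (arma::uword i = i0; i < i1; ++i) {
            colptr[i * 9 * C + row] = src[i + di];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv3x3_fwd(const arma::cube& x, const arma::mat& w,
                           const arma::vec& b) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  const arma::uword Cout = w.n_rows;
  arma::mat cols = im2col3x3(x);
  arma::mat out = w * cols;          // Cout x (H*W)
  out.each_col() += b;
  arma::cube y(H, W, Cout);
  for (arma::uword c = 0; c < Cout; ++c) {
    y.slice(c) = arma::reshape(out.row(c), H, W);
  }
  return y;
}

// Backward recomputing im2col from the cached layer input. need_dx = false
// (first layer) skips the input-gradient GEMM and scatter.
// [[Rcpp::export]]
List cpp_conv3x3_bwd(const arma::cube& x, const arma::mat& w,
                     const arma::cube& dy, bool need_dx) {
  const arma::uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const arma::uword Cout = dy.n_slices;
  arma::mat dy_mat(Cout, H * W);
  for (arma::uword c = 0; c < Cout; ++c) {
    dy_mat.row(c) = arma::vectorise(dy.slice(c)).t();
  }
  arma::mat cols = im2col3x3(x);
  arma::mat dw = dy_mat * cols.t();
  arma::vec db = arma::sum(dy_mat, 1);
  arma::cube dx(1, 1, 1, arma::fill::zeros);
  if (need_dx) {
    arma::mat dcols = w.t() * dy_mat;  // (9*Cin) x (H*W)
    dx.set_size(H, W, Cin);
    dx.zeros();
    // col2im: scatter-add back to input positions
    for (arma::uword c = 0; c < Cin; ++c) {
      arma::mat& dxs = dx.slice(c);
      for (int kr = 0; kr < 3; ++kr) {
        for (int kc = 0; kc < 3; ++kc) {
          const arma::uword row = c * 9 + kr * 3 + kc;
          const int di = kr - 1, dj = kc - 1;
          for (arma::uword j = 0; j < W; ++j) {
            const int js = (int)j + dj;
            if (js < 0 || js >= (int)W) continue;
            const arma::uword i0 = (di < 0) ? 1u : 0u;
            const arma::uword i1 = (di > 0) ? H - 1 : H;
            double* dst = dxs.colptr(js);
            for (arma::uword i = i0; i < i1; ++i) {
              dst[i + di] += dcols(row, j * H + i);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword Ho = H / 2, Wo = W / 2;  // floor: trailing row/col dropped
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);  // 0-based linear index i + j*H per channel
  arma::uword p = 0;
  for (arma::uword c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (arma::uword j = 0; j < Wo; ++j) {
      for (arma::uword i = 0; i < Ho; ++i) {
        const arma::uword r = 2 * i, s = 2 * j;
        double best = xs(r, s);
        arma::uword bi = r, bj = s;
        if (xs(r + 1, s) > best) { best = xs(r + 1, s); bi = r + 1; bj = s; }
        if (xs(r, s + 1) > best) { best = xs(r, s + 1); bi = r; bj = s + 1; }
        if (xs(r + 1, s + 1) > best) { best = xs(r + 1, s + 1); bi = r + 1; bj = s + 1; }
        y(i, j, c) = best;
        idx[c * Ho * Wo + j * Ho + i] = (int)(bi + bj * H);
        ++p;
      }
    }
  }
  (void)p;
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const IntegerVector& idx, int H, int W,
                            const arma::cube& dy) {
  const arma::uword Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    arma::mat& dxs = dx.slice(c);
    const arma::mat& dys = dy.slice(c);
    for (arma::uword j = 0; j < Wo; ++j) {
      for (arma::uword i = 0; i < Ho; ++i) {
        const int lin = idx[c * Ho * Wo + j * Ho + i];
        dxs(lin % H, lin / H) += dys(i, j);
      }
    }
  }
  return dx;
}
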