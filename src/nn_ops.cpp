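// Low-level batched 2-D ops for the segmentation networks.
//
// Activations are stored as C x (H*W*B) matrices: channels in rows, spatial
// positions column-major within an item (linear index r + c*H), items
// concatenated along columns. Convolutions are im2col + GEMM; "same" padding
// with zeros; kernel size k must be odd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat nn_im2col(const arma::mat& X, int H, int W, int B, int k) {
  const int C = X.n_rows, pad = (k - 1) / 2, HW = H * W;
  mat out(C * k * k, (uword)HW * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const uword col_out = (uword)b * HW + (uword)c * H + r;
        for (int kj = 0; kj < k; ++kj) {
          const int cc = c + kj - pad;
          if (cc < 0 || cc >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int rr = r + ki - pad;
            if (rr < 0 || rr >= H) continue;
            const uword col_in = (uword)b * HW + (uword)cc * H + rr;
            out.submat(C * (ki + k * kj), col_out,
                       C * (ki + k * kj) + C - 1, col_out) = X.col(col_in);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of nn_im2col: scatter column gradients back onto the input grid.
// [[Rcpp::export]]
arma::mat nn_col2im(const arma::mat& dcols, int C, int H, int W, int B, int k) {
  const int pad = (k - 1) / 2, HW = H * W;
  mat dX(C, (uword)HW * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const uword col_out = (uword)b * HW + (uword)c * H + r;
        for (int kj = 0; kj < k; ++kj) {
          const int cc = c + kj - pad;
          if (cc < 0 || cc >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int rr = r + ki - pad;
            if (rr < 0 || rr >= H) continue;
            const uword col_in = (uword)b * HW + (uword)cc * H + rr;
            dX.col(col_in) += dcols.submat(C * (ki + k * kj), col_out,
                                           C * (ki + k * kj) + C - 1, col_out);
          }
        }
      }
    }
  }
  return dX;
}

// 2x2 max pooling; returns pooled values and the 0-based source column of
// each maximum (per channel) for the backward pass.
// [[Rcpp::export]]
Rcpp::List nn_maxpool2(const arma::mat& X, int H, int W, int B) {
  const int C = X.n_rows, H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  mat Y(C, (uword)HW2 * B);
  umat idx(C, (uword)HW2 * B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < W2; ++c) {
      for (int r = 0; r < H2; ++r) {
        const uword out = (uword)b * HW2 + (uword)c * H2 + r;
        const uword c00 = (uword)b * HW + (uword)(2 * c) * H + 2 * r;
        const uword cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
        for (int ch = 0; ch < C; ++ch) {
          double best = X(ch, cand[0]); uword bi = cand[0];
          for (int q = 1; q < 4; ++q)
            if (X(ch, cand[q]) > best) { best = X(ch, cand[q]); bi = cand[q]; }
          Y(ch, out) = best; idx(ch, out) = bi;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat nn_maxpool2_bwd(const arma::mat& dY, const arma::umat& idx,
                          int H, int W, int B) {
  const int C = dY.n_rows;
  mat dX(C, (uword)H * W * B, fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (int ch = 0; ch < C; ++ch)
      dX(ch, idx(ch, j)) += dY(ch, j);
  return dX;
}

// Nearest-neighbour 2x up-sampling and its adjoint (2x2 sum).
// [[Rcpp::export]]
arma::mat nn_upsample2(const arma::mat& X, int H, int W, int B) {
  const int C = X.n_rows, H2 = H * 2, W2 = W * 2, HW = H * W, HW2 = H2 * W2;
  mat Y(C, (uword)HW2 * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r)
        Y.col((uword)b * HW2 + (uword)c * H2 + r) =
          X.col((uword)b * HW + (uword)(c / 2) * H + r / 2);
  return Y;
}

// [[Rcpp::export]]
arma::mat nn_upsample2_bwd(const arma::mat& dY, int H, int W, int B) {
  const int C = dY.n_rows, H2 = H * 2, W2 = W * 2, HW = H * W, HW2 = H2 * W2;
  mat dX(C, (uword)HW * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r)
        dX.col((uword)b * HW + (uword)(c / 2) * H + r / 2) +=
          dY.col((uword)b * HW2 + (uword)c * H2 + r);
  return dX;
}
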