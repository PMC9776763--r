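// Minimal convolutional kernels used by the in-package network engine.
// Layout convention: images/feature maps are R arrays dim c(H, W, C),
// column-major, so element (i, j, c) sits at i + j*H + c*H*W.  Convolutions
// are stride-1 "same" with zero padding and odd square kernels; weights are
// (k*k*Cin) x Cout matrices so forward/backward reduce to BLAS gemm on
// im2col matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col_same(const arma::cube &x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = k / 2;
  arma::mat out(k * k * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -half; dj <= half; ++dj) {
      for (int di = -half; di <= half; ++di) {
        const int row = c * k * k + (dj + half) * k + (di + half);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            out(row, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return out;
}

static arma::cube col2im_same(const arma::mat &cols, int H, int W, int C,
                              int k) {
  const int half = k / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -half; dj <= half; ++dj) {
      for (int di = -half; di <= half; ++di) {
        const int row = c * k * k + (dj + half) * k + (di + half);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += cols(row, j * H + i);
          }
        }
      }
    }
  }
  return out;
}

static void get_dims(const NumericVector &x, int &H, int &W, int &C) {
  IntegerVector d = x.attr("dim");
  H = d[0];
  W = d[1];
  C = d.size() > 2 ? d[2] : 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericMatrix w,
                               NumericVector b, int k) {
  int H, W, C;
  get_dims(x, H, W, C);
  arma::cube xc(x.begin(), H, W, C, false);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  const int Cout = wm.n_cols;
  arma::mat cols = im2col_same(xc, k);
  arma::mat y = cols.t() * wm; // (H*W) x Cout == cube memory layout
  arma::rowvec bv(b.begin(), b.size());
  y.each_row() += bv;
  NumericVector out(H * W * Cout);
  std::copy(y.begin(), y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                       int k) {
  int H, W, C;
  get_dims(x, H, W, C);
  int H2, W2, Cout;
  get_dims(dy, H2, W2, Cout);
  arma::cube xc(x.begin(), H, W, C, false);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dym(dy.begin(), H * W, Cout, false); // (H*W) x Cout view
  arma::mat cols = im2col_same(xc, k);
  arma::mat dW = cols * dym;               // (k*k*C) x Cout
  arma::rowvec db = arma::sum(dym, 0);     // 1 x Cout
  arma::mat dcols = wm * dym.t();          // (k*k*C) x (H*W)
  arma::cube dxc = col2im_same(dcols, H, W, C, k);
  NumericVector dx(H * W * C);
  std::copy(dxc.begin(), dxc.end(), dx.begin());
  dx.attr("dim") = IntegerVector::create(H, W, C);
  NumericMatrix dWout(dW.n_rows, dW.n_cols);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; returns 1-based argmax indices into the input.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x) {
  int H, W, C;
  get_dims(x, H, W, C);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int lin = (2 * i + di) + (2 * j + dj) * H + c * H * W;
            if (x[lin] > best) {
              best = x[lin];
              besti = lin;
            }
          }
        }
        const int o = i + j * Ho + c * Ho * Wo;
        out[o] = best;
        idx[o] = besti + 1;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector in_dim) {
  NumericVector dx(in_dim[0] * in_dim[1] * in_dim[2]);
  for (int t = 0; t < dy.size(); ++t) dx[idx[t] - 1] += dy[t];
  dx.attr("dim") = in_dim;
  return dx;
}

// Nearest-neighbour upsampling by an integer factor.
// [[Rcpp::export]]
NumericVector cpp_upsample_forward(NumericVector x, int f) {
  int H, W, C;
  get_dims(x, H, W, C);
  const int Ho = H * f, Wo = W * f;
  NumericVector out(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        out[i + j * Ho + c * Ho * Wo] = x[(i / f) + (j / f) * H + c * H * W];
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_backward(NumericVector dy, int f,
                                    IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2];
  const int Ho = H * f, Wo = W * f;
  NumericVector dx(H * W * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx[(i / f) + (j / f) * H + c * H * W] +=
            dy[i + j * Ho + c * Ho * Wo];
  dx.attr("dim") = in_dim;
  return dx;
}
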