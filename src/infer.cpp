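// Folded-BN inference kernel for the detection network. Tensors are laid
// out channel-major with zero pad columns between windows so the composite
// (depthwise x pointwise) convolution of every residual block becomes a
// handful of large dgemm calls on contiguous column ranges.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".detect_infer_cpp")]]
arma::vec detect_infer_cpp(const arma::cube& X, const arma::mat& stemW,
                           const arma::vec& stemb, const List& blockW,
                           const List& blockb, const arma::mat& headW,
                           const arma::vec& headb, int kernel) {
  const int N = X.n_rows, W = X.n_cols, F = X.n_slices;
  const int pad = (kernel - 1) / 2;
  const int Wp = W + 2 * pad;
  const arma::uword M = (arma::uword) N * Wp;
  const int C = stemW.n_cols;

  arma::mat Xp(F, M, arma::fill::zeros);
  for (int f = 0; f < F; ++f) {
    for (int w = 0; w < W; ++w) {
      for (int n = 0; n < N; ++n) {
        Xp(f, (arma::uword) n * Wp + pad + w) = X(n, w, f);
      }
    }
  }
  arma::mat H = stemW.t() * Xp;
  H.each_col() += stemb;
  auto zero_pads = [&](arma::mat& A) {
    for (int n = 0; n < N; ++n) {
      for (int p = 0; p < pad; ++p) {
        A.col((arma::uword) n * Wp + p).zeros();
        A.col((arma::uword) n * Wp + Wp - 1 - p).zeros();
      }
    }
  };
  zero_pads(H);

  const int n_blocks = blockW.size();
  for (int b = 0; b < n_blocks; ++b) {
    arma::mat Wc = as<arma::mat>(blockW[b]);       // (k*C) x C
    arma::vec bb = as<arma::vec>(blockb[b]);
    arma::mat Z(C, M, arma::fill::zeros);
    for (int o = 0; o < kernel; ++o) {
      int s = o - pad;
      arma::uword lo = (arma::uword) std::max(0, -s);
      arma::uword hi = M - 1 - (arma::uword) std::max(0, s);
      arma::mat Wt = Wc.rows(o * C, (o + 1) * C - 1).t();
      Z.cols(lo, hi) += Wt * H.cols(lo + s, hi + s);
    }
    Z.each_col() += bb;
    Z.transform([](double v) { return v > 0 ? v : 0.0; });
    H += Z;
    zero_pads(H);
  }

  // position-aware linear head over the flattened window (rows of headW
  // ordered window-position-major, channel-minor)
  arma::vec out(N);
  for (int n = 0; n < N; ++n) {
    double l0 = headb(0), l1 = headb(1);
    for (int w = 0; w < W; ++w) {
      const arma::uword col = (arma::uword) n * Wp + pad + w;
      for (int c = 0; c < C; ++c) {
        double h = H(c, col);
        l0 += headW(w * C + c, 0) * h;
        l1 += headW(w * C + c, 1) * h;
      }
    }
    out(n) = 1.0 / (1.0 + std::exp(l0 - l1));
  }
  return out;
}
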