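// Minimal stride-1 "same" convolution, 2x2 max-pooling and their gradients
// for the small weakly supervised tumour classifier. Batches are R arrays
// (H, W, C, N) in column-major order; im2col turns each image into a
// (C*k*k) x (H*W) matrix so convolution becomes one BLAS gemm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::cube cube_view(NumericVector& x, int H, int W, int C, int n) {
  return arma::cube(x.begin() + (size_t)n * H * W * C, H, W, C, false, true);
}

static inline NumericVector make_array4(int d1, int d2, int d3, int d4) {
  NumericVector out((size_t)d1 * d2 * d3 * d4);
  out.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return out;
}

// row layout of the patch matrix: channel-major, then kernel column, then
// kernel row -> row = c*k*k + dj*k + di
static void im2col(const arma::cube& x, int k, arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, P = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dj - P;
          const bool wok = (ws >= 0 && ws < W);
          for (int h = 0; h < H; ++h) {
            const int hs = h + di - P;
            double v = 0.0;
            if (wok && hs >= 0 && hs < H) v = x(hs, ws, c);
            cols(row, (size_t)w * H + h) = v;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& cols, int k, arma::cube& dx) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices, P = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dj - P;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int hs = h + di - P;
            if (hs < 0 || hs >= H) continue;
            dx(hs, ws, c) += cols(row, (size_t)w * H + h);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericMatrix weight, NumericVector bias, int k) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  arma::mat Wm(weight.begin(), weight.nrow(), weight.ncol(), false);
  const int F = Wm.n_rows;
  arma::vec bv(bias.begin(), F, false);
  NumericVector out = make_array4(H, W, F, N);
  arma::mat cols(C * k * k, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    arma::cube xc = cube_view(x, H, W, C, n);
    im2col(xc, k, cols);
    arma::mat o = Wm * cols;
    o.each_col() += bv;
    arma::mat ot = o.t();  // (H*W) x F: contiguous per output channel
    std::copy(ot.begin(), ot.end(), out.begin() + (size_t)n * H * W * F);
  }
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericMatrix weight, NumericVector dout, int k) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  arma::mat Wm(weight.begin(), weight.nrow(), weight.ncol(), false);
  const int F = Wm.n_rows;
  arma::mat dW(F, C * k * k, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  NumericVector dx = make_array4(H, W, C, N);
  arma::mat cols(C * k * k, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    arma::cube xc = cube_view(x, H, W, C, n);
    im2col(xc, k, cols);
    arma::mat dot(dout.begin() + (size_t)n * H * W * F, (size_t)H * W, F, false, true);
    arma::mat dm2 = dot.t();  // F x (H*W)
    dW += dm2 * cols.t();
    db += arma::sum(dm2, 1);
    arma::mat dcols = Wm.t() * dm2;
    arma::cube dxc = cube_view(dx, H, W, C, n);
    col2im_acc(dcols, k, dxc);
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = make_array4(Ho, Wo, C, N);
  IntegerVector arg((size_t)Ho * Wo * C * N);  // offset dr + 2*dc in the 2x2 cell
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++q) {
          double best = -1e300;
          int bestk = 0;
          for (int dc = 0; dc < 2; ++dc) {
            for (int dr = 0; dr < 2; ++dr) {
              const double v = plane[(size_t)(2 * wo + dc) * H + (2 * ho + dr)];
              if (v > best) { best = v; bestk = dr + 2 * dc; }
            }
          }
          out[q] = best;
          arg[q] = bestk;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector arg, IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx = make_array4(H, W, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    double* xp = dx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* plane = xp + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++q) {
          const int k = arg[q];
          const int dr = k % 2, dc = k / 2;
          plane[(size_t)(2 * wo + dc) * H + (2 * ho + dr)] += dout[q];
        }
      }
    }
  }
  return dx;
}
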