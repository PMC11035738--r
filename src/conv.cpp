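// Compiled numerics for the small convolutional identity classifier and the
// region-restricted Gaussian blur. Batches are passed as (H*W*C) x N
// matrices whose columns are R arrays in (row, col, channel) order, so no
// copying happens at the R/C++ boundary.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Unpack one image (column-major H x W x C) into a (C*k*k) x (Ho*Wo) patch
// matrix. Patch row index = c*k*k + dj*k + di; output column = wo*Ho + ho.
static void im2col_one(const double* x, int H, int W, int C,
                       int k, int stride, int pad, arma::mat& col) {
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      double* dst = col.colptr(wo * Ho + ho);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (std::size_t)c * H * W;
        for (int dj = 0; dj < k; ++dj) {
          const int wi = w0 + dj;
          const bool win = (wi >= 0 && wi < W);
          for (int di = 0; di < k; ++di) {
            const int hi = h0 + di;
            dst[c * k * k + dj * k + di] =
              (win && hi >= 0 && hi < H) ? xc[(std::size_t)wi * H + hi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-gradient matrix back onto the image grid
// (adjoint of im2col_one).
static void col2im_one(const arma::mat& col, int H, int W, int C,
                       int k, int stride, int pad, double* dx) {
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    const int w0 = wo * stride - pad;
    for (int ho = 0; ho < Ho; ++ho) {
      const int h0 = ho * stride - pad;
      const double* src = col.colptr(wo * Ho + ho);
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (std::size_t)c * H * W;
        for (int dj = 0; dj < k; ++dj) {
          const int wi = w0 + dj;
          if (wi < 0 || wi >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int hi = h0 + di;
            if (hi < 0 || hi >= H) continue;
            xc[(std::size_t)wi * H + hi] += src[c * k * k + dj * k + di];
          }
        }
      }
    }
  }
}

// Forward pass of one convolution layer over a batch.
// x: (H*W*Cin) x N, wmat: Cout x (Cin*k*k). Returns (Ho*Wo*Cout) x N,
// optionally ReLU-rectified.
// [[Rcpp::export(name = ".conv_forward")]]
arma::mat conv_forward(const arma::mat& x, int H, int W, int Cin,
                       const arma::mat& wmat, const arma::vec& bias,
                       int k, int stride, int pad, bool relu) {
  const int N = x.n_cols;
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  const int Cout = wmat.n_rows;
  arma::mat out((std::size_t)Ho * Wo * Cout, N);
  arma::mat col(Cin * k * k, (std::size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.colptr(n), H, W, Cin, k, stride, pad, col);
    arma::mat y = wmat * col;          // Cout x (Ho*Wo)
    y.each_col() += bias;
    if (relu) y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    // (Ho*Wo) x Cout layout per image = t(y)
    arma::mat yt = y.t();
    std::copy(yt.memptr(), yt.memptr() + yt.n_elem, out.colptr(n));
  }
  return out;
}

// Backward pass of one convolution layer over a batch. `y` is the layer's
// forward output (post-ReLU when relu = TRUE) used for the rectifier mask.
// Returns dx ((H*W*Cin) x N), dw, db.
// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward(const arma::mat& x, const arma::mat& y,
                   const arma::mat& dy, int H, int W, int Cin,
                   const arma::mat& wmat, int k, int stride, int pad,
                   bool relu) {
  const int N = x.n_cols;
  const int Ho = conv_out(H, k, stride, pad);
  const int Wo = conv_out(W, k, stride, pad);
  const int Cout = wmat.n_rows;
  const std::size_t HW = (std::size_t)Ho * Wo;
  arma::mat dx((std::size_t)H * W * Cin, N, arma::fill::zeros);
  arma::mat dw(arma::size(wmat), arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(Cin * k * k, HW);
  for (int n = 0; n < N; ++n) {
    // dy column -> Cout x (Ho*Wo), applying the ReLU mask from y
    arma::mat dyn(Cout, HW);
    const double* dyp = dy.colptr(n);
    const double* yp = y.colptr(n);
    for (int c = 0; c < Cout; ++c)
      for (std::size_t s = 0; s < HW; ++s) {
        const std::size_t idx = c * HW + s;
        double g = dyp[idx];
        if (relu && yp[idx] <= 0.0) g = 0.0;
        dyn(c, s) = g;
      }
    im2col_one(x.colptr(n), H, W, Cin, k, stride, pad, col);
    dw += dyn * col.t();
    db += arma::sum(dyn, 1);
    arma::mat dcol = wmat.t() * dyn;   // (Cin*k*k) x (Ho*Wo)
    col2im_one(dcol, H, W, Cin, k, stride, pad, dx.colptr(n));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Half-sample symmetric reflection: ... c b a | a b c ... | c b a
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable convolution of a single-channel image with a symmetric 1-D
// kernel (odd length), reflective border handling. Equivalent to the full
// 2-D convolution with the outer-product kernel.
// [[Rcpp::export(name = ".sep_conv_reflect")]]
NumericMatrix sep_conv_reflect(const NumericMatrix& img,
                               const NumericVector& g) {
  const int H = img.nrow(), W = img.ncol(), k = g.size();
  const int r = k / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // rows (vertical pass)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += g[d + r] * img(reflect_idx(h + d, H), w);
      tmp(h, w) = acc;
    }
  // columns (horizontal pass)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += g[d + r] * tmp(h, reflect_idx(w + d, W));
      out(h, w) = acc;
    }
  return out;
}
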