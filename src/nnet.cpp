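// 3D convolution / pooling primitives for the U-Net, via im2col + BLAS GEMM.
// Tensors are R arrays with dim (D, H, W, C), column-major, D fastest.
// Weights for a k^3 convolution are arrays with dim (k, k, k, Cin, Cout),
// flattened so that column index = offset + k^3 * cin matches im2col order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline size_t tidx(int i, int j, int k, int c, int D, int H, int W) {
  return (size_t)i + (size_t)D * (j + (size_t)H * (k + (size_t)W * c));
}

// Convolution arithmetic runs in single precision: the GEMMs here are
// memory-bound (small K dimension), so float halves the traffic, and NN
// training is insensitive to the reduced precision.

// im2col with zero padding (k odd, pad = k/2, stride 1): rows = voxels,
// cols = k^3 * Cin.
arma::fmat im2col(const double *x, int D, int H, int W, int C, int k) {
  int p = k / 2;
  size_t N = (size_t)D * H * W;
  arma::fmat col(N, (size_t)k * k * k * C);
  for (int c = 0; c < C; ++c) {
    int o = 0;
    for (int dz = -p; dz <= p; ++dz)
      for (int dy = -p; dy <= p; ++dy)
        for (int dx = -p; dx <= p; ++dx, ++o) {
          float *dst = col.colptr((size_t)o + (size_t)k * k * k * c);
          size_t r = 0;
          for (int w = 0; w < W; ++w) {
            int wz = w + dz;
            for (int h = 0; h < H; ++h) {
              int hy = h + dy;
              bool okp = wz >= 0 && wz < W && hy >= 0 && hy < H;
              if (!okp) {
                for (int d = 0; d < D; ++d) dst[r++] = 0.0;
              } else {
                const double *src = x + tidx(0, hy, wz, c, D, H, W);
                for (int d = 0; d < D; ++d) {
                  int di = d + dx;
                  dst[r++] = (di >= 0 && di < D) ? (float)src[di] : 0.0f;
                }
              }
            }
          }
        }
  }
  return col;
}

// scatter-add transpose of im2col
void col2im_add(const arma::fmat &col, double *gx, int D, int H, int W, int C, int k) {
  int p = k / 2;
  for (int c = 0; c < C; ++c) {
    int o = 0;
    for (int dz = -p; dz <= p; ++dz)
      for (int dy = -p; dy <= p; ++dy)
        for (int dx = -p; dx <= p; ++dx, ++o) {
          const float *src = col.colptr((size_t)o + (size_t)k * k * k * c);
          size_t r = 0;
          for (int w = 0; w < W; ++w) {
            int wz = w + dz;
            for (int h = 0; h < H; ++h) {
              int hy = h + dy;
              bool okp = wz >= 0 && wz < W && hy >= 0 && hy < H;
              if (!okp) { r += D; continue; }
              double *dstc = gx + tidx(0, hy, wz, c, D, H, W);
              for (int d = 0; d < D; ++d, ++r) {
                int di = d + dx;
                if (di >= 0 && di < D) dstc[di] += src[r];
              }
            }
          }
        }
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, NumericVector b, int k) {
  int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  int Co = b.size();
  arma::fmat col = im2col(x.begin(), D, H, W, Ci, k);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double *>(w.begin()), (size_t)k * k * k * Ci, Co, false, true));
  arma::fmat Y = col * Wm;
  arma::frowvec bv = arma::conv_to<arma::frowvec>::from(
      arma::rowvec(const_cast<double *>(b.begin()), Co, false, true));
  Y.each_row() += bv;
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(D, H, W, Co);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdim, NumericVector w,
                   NumericVector gy, int k, int Co) {
  int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  size_t N = (size_t)D * H * W;
  arma::fmat col = im2col(x.begin(), D, H, W, Ci, k);
  arma::fmat GY = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double *>(gy.begin()), N, Co, false, true));
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double *>(w.begin()), (size_t)k * k * k * Ci, Co, false, true));
  arma::fmat GW = col.t() * GY;
  arma::frowvec GB = arma::sum(GY, 0);
  arma::fmat Gcol = GY * Wm.t();
  NumericVector gx((size_t)D * H * W * Ci); // zero-initialised
  col2im_add(Gcol, gx.begin(), D, H, W, Ci, k);
  gx.attr("dim") = xdim;
  NumericVector gw(GW.begin(), GW.end());
  gw.attr("dim") = IntegerVector::create(k, k, k, Ci, Co);
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}

// 2x2x2 max pooling, stride 2. Returns pooled tensor and argmax indices
// (1-based into the flattened input) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdim) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int d2 = D / 2, h2 = H / 2, w2 = W / 2;
  NumericVector y((size_t)d2 * h2 * w2 * C);
  IntegerVector arg(y.size());
  size_t r = 0;
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < w2; ++w)
      for (int h = 0; h < h2; ++h)
        for (int d = 0; d < d2; ++d, ++r) {
          double best = R_NegInf;
          size_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t id = tidx(2 * d + dx, 2 * h + dy, 2 * w + dz, c, D, H, W);
                if (x[id] > best) { best = x[id]; bidx = id; }
              }
          y[r] = best;
          arg[r] = (int)bidx + 1;
        }
  y.attr("dim") = IntegerVector::create(d2, h2, w2, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector arg, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t r = 0; r < gy.size(); ++r) gx[arg[r] - 1] += gy[r];
  gx.attr("dim") = xdim;
  return gx;
}

// 2x nearest-neighbour upsampling and its adjoint.
// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, IntegerVector xdim) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)D2 * H2 * W2 * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h)
        for (int d = 0; d < D2; ++d)
          y[tidx(d, h, w, c, D2, H2, W2)] = x[tidx(d / 2, h / 2, w / 2, c, D, H, W)];
  y.attr("dim") = IntegerVector::create(D2, H2, W2, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(NumericVector gy, IntegerVector xdim) {
  int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  int D2 = 2 * D, H2 = 2 * H, W2 = 2 * W;
  NumericVector gx((size_t)D * H * W * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h)
        for (int d = 0; d < D2; ++d)
          gx[tidx(d / 2, h / 2, w / 2, c, D, H, W)] += gy[tidx(d, h, w, c, D2, H2, W2)];
  gx.attr("dim") = xdim;
  return gx;
}
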