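// 3-D convolution kernels for the volumetric encoder.
//
// Layout conventions (match the R side):
//  * feature maps are stored channel-first: dim = (C, X, Y, Z), column-major,
//    so the C channel values of one voxel are contiguous;
//  * weights are (C_out x C_in * k^3) matrices whose column index is
//    c + C_in * o, with o = kx + k*(ky + k*kz) the kernel-offset index;
//  * convolutions use zero padding `pad` and isotropic stride `stride`.
//
// Forward and backward are im2col + GEMM; the backward pass recomputes the
// column matrix instead of caching it, trading a memory-bound pass for not
// holding one large buffer per layer.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>

using namespace Rcpp;
using arma::mat;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col(const double* x, int C, int X, int Y, int Z,
                   int k, int stride, int pad, mat& cols) {
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const size_t Cb = (size_t)C * sizeof(double);
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int j = ox + OX * (oy + OY * oz);
        double* cj = cols.colptr(j);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              const int o = kx + k * (ky + k * kz);
              double* dst = cj + (size_t)C * o;
              if (ix < 0 || iy < 0 || iz < 0 || ix >= X || iy >= Y || iz >= Z) {
                std::memset(dst, 0, Cb);
              } else {
                std::memcpy(dst, x + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz)), Cb);
              }
            }
          }
        }
      }
    }
  }
}

static void col2im_add(const mat& cols, double* dx, int C, int X, int Y, int Z,
                       int k, int stride, int pad) {
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int j = ox + OX * (oy + OY * oz);
        const double* cj = cols.colptr(j);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= X) continue;
              const int o = kx + k * (ky + k * kz);
              const double* src = cj + (size_t)C * o;
              double* dst = dx + (size_t)C * (ix + (size_t)X * (iy + (size_t)Y * iz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(const NumericVector& x, const IntegerVector& dims,
                            const NumericMatrix& W, const NumericVector& b,
                            int k, int stride, int pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Cout = W.nrow();
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const int N = OX * OY * OZ;
  if (W.ncol() != C * k * k * k)
    stop("weight matrix has %d columns, expected %d", W.ncol(), C * k * k * k);
  mat cols((size_t)C * k * k * k, N);
  im2col(x.begin(), C, X, Y, Z, k, stride, pad, cols);
  NumericVector out((size_t)Cout * N);
  mat Wm(const_cast<double*>(W.begin()), Cout, W.ncol(), false, true);
  arma::vec bm(const_cast<double*>(b.begin()), Cout, false, true);
  mat Ym(out.begin(), Cout, N, false, true);
  Ym = Wm * cols;
  Ym.each_col() += bm;
  out.attr("dim") = IntegerVector::create(Cout, OX, OY, OZ);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(const NumericVector& x, const IntegerVector& dims,
                   const NumericMatrix& W, const NumericVector& dy,
                   int k, int stride, int pad, bool need_dx) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int Cout = W.nrow();
  const int OX = out_extent(X, k, stride, pad);
  const int OY = out_extent(Y, k, stride, pad);
  const int OZ = out_extent(Z, k, stride, pad);
  const int N = OX * OY * OZ;
  mat cols((size_t)C * k * k * k, N);
  im2col(x.begin(), C, X, Y, Z, k, stride, pad, cols);
  mat Wm(const_cast<double*>(W.begin()), Cout, W.ncol(), false, true);
  mat dYm(const_cast<double*>(dy.begin()), Cout, N, false, true);

  NumericMatrix dW(Cout, W.ncol());
  mat dWm(dW.begin(), Cout, W.ncol(), false, true);
  dWm = dYm * cols.t();

  NumericVector db(Cout);
  arma::vec dbm(db.begin(), Cout, false, true);
  dbm = arma::sum(dYm, 1);

  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dW"] = dW, _["db"] = db);
  mat dcols = Wm.t() * dYm;
  NumericVector dx((size_t)C * X * Y * Z);  // zero-initialised
  col2im_add(dcols, dx.begin(), C, X, Y, Z, k, stride, pad);
  dx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
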