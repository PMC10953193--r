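#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps are stored as (nvox x C) matrices whose rows linearise the
// (z, y, x) grid with z fastest, i.e. row = z + Z*(y + Y*x).  This matches
// the memory layout of an R array with dim c(Z, Y, X, C), so R passes
// feature tensors without copying or permuting.  Convolution is im2col +
// BLAS; the im2col matrix is returned to the caller so the backward pass
// can reuse it for the weight gradient.

static inline int conv_out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col: rows = output voxels (z fastest), cols = c*k^3 + (kz + k*(ky + k*kx)).
// Channel-major column blocks keep each group's columns contiguous.
static arma::mat im2col3(const arma::mat& x, int Z, int Y, int X,
                         int k, int stride, int pad,
                         int Zo, int Yo, int Xo) {
  const int C = x.n_cols, K3 = k * k * k;
  arma::mat col(static_cast<size_t>(Zo) * Yo * Xo, static_cast<size_t>(C) * K3);
  // every element is written exactly once: valid voxels copied, padding zeroed
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky)
        for (int kz = 0; kz < k; ++kz) {
          double* cc = col.colptr(static_cast<size_t>(c) * K3 + kz + k * (ky + k * kx));
          for (int xo = 0; xo < Xo; ++xo) {
            const int xi = xo * stride - pad + kx;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + ky;
              double* dst = cc + static_cast<size_t>(Zo) * (yo + static_cast<size_t>(Yo) * xo);
              if (xi < 0 || xi >= X || yi < 0 || yi >= Y) {
                std::fill(dst, dst + Zo, 0.0);
                continue;
              }
              const double* src = xc + static_cast<size_t>(Z) * (yi + static_cast<size_t>(Y) * xi);
              if (stride == 1) {
                const int lo = std::max(0, pad - kz);
                const int hi = std::min(Zo - 1, Z - 1 + pad - kz);
                const int off = kz - pad;
                std::fill(dst, dst + std::max(lo, 0), 0.0);
                if (hi >= lo)
                  std::memcpy(dst + lo, src + lo + off,
                              static_cast<size_t>(hi - lo + 1) * sizeof(double));
                std::fill(dst + std::max(hi + 1, 0), dst + Zo, 0.0);
              } else {
                for (int zo = 0; zo < Zo; ++zo) {
                  const int zi = zo * stride - pad + kz;
                  dst[zo] = (zi < 0 || zi >= Z) ? 0.0 : src[zi];
                }
              }
            }
          }
        }
  }
  return col;
}

// col2im: scatter-add transpose of im2col.
static arma::mat col2im3(const arma::mat& col, int Z, int Y, int X, int C,
                         int k, int stride, int pad,
                         int Zo, int Yo, int Xo) {
  const int K3 = k * k * k;
  arma::mat x(static_cast<size_t>(Z) * Y * X, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = x.colptr(c);
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky)
        for (int kz = 0; kz < k; ++kz) {
          const double* cc = col.colptr(static_cast<size_t>(c) * K3 + kz + k * (ky + k * kx));
          for (int xo = 0; xo < Xo; ++xo) {
            const int xi = xo * stride - pad + kx;
            if (xi < 0 || xi >= X) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              const int yi = yo * stride - pad + ky;
              if (yi < 0 || yi >= Y) continue;
              double* dst = xc + static_cast<size_t>(Z) * (yi + static_cast<size_t>(Y) * xi);
              const double* src = cc + static_cast<size_t>(Zo) * (yo + static_cast<size_t>(Yo) * xo);
              if (stride == 1) {
                const int lo = std::max(0, pad - kz);
                const int hi = std::min(Zo - 1, Z - 1 + pad - kz);
                const int off = kz - pad;
                for (int zo = lo; zo <= hi; ++zo) dst[zo + off] += src[zo];
              } else {
                for (int zo = 0; zo < Zo; ++zo) {
                  const int zi = zo * stride - pad + kz;
                  if (zi < 0 || zi >= Z) continue;
                  dst[zi] += src[zo];
                }
              }
            }
          }
        }
  }
  return x;
}

// W: (k^3 * Cin/groups) x Cout; column j serves output channel j, reading
// input channels of group g = j / (Cout/groups).
// [[Rcpp::export]]
List conv3d_fwd_cpp(const arma::mat& x, IntegerVector dims,
                    const arma::mat& W, const arma::vec& b,
                    int k, int stride, int pad, int groups,
                    bool return_col = false) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int Cin = x.n_cols, Cout = W.n_cols, K3 = k * k * k;
  const int Cin_g = Cin / groups, Cout_g = Cout / groups;
  const int Zo = conv_out_size(Z, k, stride, pad);
  const int Yo = conv_out_size(Y, k, stride, pad);
  const int Xo = conv_out_size(X, k, stride, pad);
  arma::mat col = im2col3(x, Z, Y, X, k, stride, pad, Zo, Yo, Xo);
  arma::mat y(col.n_rows, Cout);
  for (int g = 0; g < groups; ++g) {
    y.cols(g * Cout_g, (g + 1) * Cout_g - 1) =
      col.cols(static_cast<size_t>(g) * Cin_g * K3, static_cast<size_t>(g + 1) * Cin_g * K3 - 1) *
      W.cols(g * Cout_g, (g + 1) * Cout_g - 1);
  }
  y.each_row() += b.t();
  if (return_col) {
    XPtr<arma::mat> colp(new arma::mat(std::move(col)), true);
    return List::create(_["y"] = y,
                        _["odims"] = IntegerVector::create(Zo, Yo, Xo),
                        _["col"] = colp);
  }
  return List::create(_["y"] = y,
                      _["odims"] = IntegerVector::create(Zo, Yo, Xo));
}

// Backward from the cached im2col matrix; dx is skipped for the first
// layer of the network, whose input gradient nobody consumes.
// [[Rcpp::export]]
List conv3d_bwd_cpp(SEXP col_ptr, IntegerVector dims,
                    const arma::mat& W, const arma::mat& dy,
                    int k, int stride, int pad, int groups,
                    bool need_dx = true) {
  const arma::mat& col = *XPtr<arma::mat>(col_ptr);
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int Cout = W.n_cols, K3 = k * k * k;
  const int Cin = (W.n_rows / K3) * groups;
  const int Cin_g = Cin / groups, Cout_g = Cout / groups;
  const int Zo = conv_out_size(Z, k, stride, pad);
  const int Yo = conv_out_size(Y, k, stride, pad);
  const int Xo = conv_out_size(X, k, stride, pad);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dcol;
  if (need_dx) dcol.set_size(col.n_rows, col.n_cols);
  for (int g = 0; g < groups; ++g) {
    const arma::mat dyg = dy.cols(g * Cout_g, (g + 1) * Cout_g - 1);
    dW.cols(g * Cout_g, (g + 1) * Cout_g - 1) =
      col.cols(static_cast<size_t>(g) * Cin_g * K3, static_cast<size_t>(g + 1) * Cin_g * K3 - 1).t() * dyg;
    if (need_dx)
      dcol.cols(static_cast<size_t>(g) * Cin_g * K3, static_cast<size_t>(g + 1) * Cin_g * K3 - 1) =
        dyg * W.cols(g * Cout_g, (g + 1) * Cout_g - 1).t();
  }
  arma::vec db = arma::sum(dy, 0).t();
  if (!need_dx)
    return List::create(_["dW"] = dW, _["db"] = db);
  arma::mat dx = col2im3(dcol, Z, Y, X, Cin, k, stride, pad, Zo, Yo, Xo);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
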