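#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensors are stored as (N*H*W) x C matrices, row index (n*W + w)*H + h
// (h fastest, then w, then n), so each column reshapes to an H x W x N
// array without permutation. im2col patch columns are ordered channel-major:
// column index c*k*k + kw*k + kh. The stride-1 inner loops run over
// contiguous memory and use memcpy / vectorizable additions.

// [[Rcpp::export]]
NumericMatrix nn_im2col(const NumericMatrix& x, int N, int H, int W,
                        int k, int stride, int pad) {
  const int C = x.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(N * Ho * Wo, k * k * C);  // zero-initialized
  const double* px = REAL(x);
  double* pout = REAL(out);
  const R_xlen_t nin = x.nrow(), nout = out.nrow();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (R_xlen_t)c * nin;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* oc = pout + (R_xlen_t)(c * k * k + kw * k + kh) * nout;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            double* po = oc + (R_xlen_t)(n * Wo + wo) * Ho;
            const double* pi = xc + (R_xlen_t)(n * W + wi) * H;
            if (stride == 1) {
              const int lo = std::max(0, pad - kh);
              const int hi = std::min(Ho, H + pad - kh);
              if (hi > lo)
                std::memcpy(po + lo, pi + lo - pad + kh,
                            (size_t)(hi - lo) * sizeof(double));
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi_ = ho * stride - pad + kh;
                if (hi_ >= 0 && hi_ < H) po[ho] = pi[hi_];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add adjoint of nn_im2col: dcol is (N*Ho*Wo) x (k*k*C).
// [[Rcpp::export]]
NumericMatrix nn_col2im(const NumericMatrix& dcol, int N, int H, int W,
                        int k, int stride, int pad) {
  const int C = dcol.ncol() / (k * k);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix dx(N * H * W, C);
  const double* pcol = REAL(dcol);
  double* pdx = REAL(dx);
  const R_xlen_t nin = dx.nrow(), nout = dcol.nrow();
  for (int c = 0; c < C; ++c) {
    double* xc = pdx + (R_xlen_t)c * nin;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* oc = pcol + (R_xlen_t)(c * k * k + kw * k + kh) * nout;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            const double* po = oc + (R_xlen_t)(n * Wo + wo) * Ho;
            double* pi = xc + (R_xlen_t)(n * W + wi) * H;
            if (stride == 1) {
              const int lo = std::max(0, pad - kh);
              const int hi = std::min(Ho, H + pad - kh);
              double* pt = pi - pad + kh;
              for (int ho = lo; ho < hi; ++ho) pt[ho] += po[ho];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi_ = ho * stride - pad + kh;
                if (hi_ >= 0 && hi_ < H) pi[hi_] += po[ho];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// Per-channel max pooling; records the winning input row (1-based) so the
// backward pass is an exact scatter.
// [[Rcpp::export]]
List nn_maxpool_fwd(const NumericMatrix& x, int N, int H, int W,
                    int k, int stride, int pad) {
  const int C = x.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix y(N * Ho * Wo, C);
  IntegerMatrix idx(N * Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = REAL(x) + (R_xlen_t)c * x.nrow();
    for (int n = 0; n < N; ++n) {
      for (int wo = 0; wo < Wo; ++wo) {
        const R_xlen_t orow = (R_xlen_t)(n * Wo + wo) * Ho;
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const int r = (n * W + wi) * H + hi;
              const double v = xc[r];
              if (v > best) { best = v; besti = r; }
            }
          }
          y(orow + ho, c) = best;
          idx(orow + ho, c) = besti + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix nn_maxpool_bwd(const NumericMatrix& dy, const IntegerMatrix& idx,
                             int n_in) {
  const int C = dy.ncol();
  NumericMatrix dx(n_in, C);
  for (int c = 0; c < C; ++c) {
    double* pdx = REAL(dx) + (R_xlen_t)c * n_in;
    const double* pdy = REAL(dy) + (R_xlen_t)c * dy.nrow();
    const int* pidx = INTEGER(idx) + (R_xlen_t)c * idx.nrow();
    for (int r = 0; r < dy.nrow(); ++r) pdx[pidx[r] - 1] += pdy[r];
  }
  return dx;
}
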