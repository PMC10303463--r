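#include <Rcpp.h>
using namespace Rcpp;

// 3x3 im2col with zero padding, batched. Input x: (H*W*B) x C activation
// matrix; rows are column-major spatial order (row index fastest) with the
// B image blocks contiguous. Output: (H*W*B) x (9*C) with offset-major
// column blocks: columns (o-1)*C + (1:C) hold offset o, o enumerated
// dx-major over (dx, dy) in {0,1,2}^2 (matching the R reference layout).
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericMatrix x, int H, int W, int B = 1) {
  int C = x.ncol();
  size_t n = (size_t)H * W;
  size_t nB = n * B;
  NumericMatrix cols(nB, 9 * C);
  const double* xp = REAL(x);
  double* cp = REAL(cols);
  int o = 0;
  for (int dx = 0; dx < 3; ++dx) {
    for (int dy = 0; dy < 3; ++dy, ++o) {
      int rlo = std::max(0, 1 - dy), rhi = std::min(H, H + 1 - dy);
      int clo = std::max(0, 1 - dx), chi = std::min(W, W + 1 - dx);
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < B; ++b) {
          double* dst = cp + nB * (o * C + c) + n * b;
          const double* src = xp + nB * c + n * b;
          for (int cc = clo; cc < chi; ++cc) {
            int src_c = cc + dx - 1;
            const double* s = src + (size_t)H * src_c + (rlo + dy - 1);
            double* d = dst + (size_t)H * cc + rlo;
            std::copy(s, s + (rhi - rlo), d);
          }
        }
      }
    }
  }
  return cols;
}

// adjoint: scatter-add (H*W*B) x (9*C) gradients back to (H*W*B) x C
// [[Rcpp::export]]
NumericMatrix cpp_col2im3(NumericMatrix dcols, int H, int W, int B = 1) {
  int C = dcols.ncol() / 9;
  size_t n = (size_t)H * W;
  size_t nB = n * B;
  NumericMatrix dx_(nB, C);
  const double* gp = REAL(dcols);
  double* op = REAL(dx_);
  int o = 0;
  for (int dx = 0; dx < 3; ++dx) {
    for (int dy = 0; dy < 3; ++dy, ++o) {
      int rlo = std::max(0, 1 - dy), rhi = std::min(H, H + 1 - dy);
      int clo = std::max(0, 1 - dx), chi = std::min(W, W + 1 - dx);
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < B; ++b) {
          const double* src = gp + nB * (o * C + c) + n * b;
          double* dst = op + nB * c + n * b;
          for (int cc = clo; cc < chi; ++cc) {
            int dst_c = cc + dx - 1;
            const double* s = src + (size_t)H * cc + rlo;
            double* d = dst + (size_t)H * dst_c + (rlo + dy - 1);
            for (int r = 0; r < rhi - rlo; ++r) d[r] += s[r];
          }
        }
      }
    }
  }
  return dx_;
}
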