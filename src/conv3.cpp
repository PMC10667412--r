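// im2col / col2im for 3x3x3 "same" convolutions on (X, Y, Z, C) arrays.
// These are pure data-movement kernels; the convolution itself is a BLAS
// matrix product on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  NumericMatrix out(no_init(N, 27 * C));  // every element is written below
  const double *px = x.begin();
  double *po = out.begin();
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    for (int c = 0; c < C; ++c) {
      double *col = po + ((R_xlen_t)(o * C + c)) * N;
      const double *src = px + (R_xlen_t)c * N;
      for (int z = 0; z < Z; ++z) {
        const int sz = z + dz;
        for (int y = 0; y < Y; ++y) {
          const int sy = y + dy;
          double *dst = col + (R_xlen_t)(z * Y + y) * X;
          if (sz < 0 || sz >= Z || sy < 0 || sy >= Y) {
            std::fill(dst, dst + X, 0.0);
            continue;
          }
          const double *row = src + (R_xlen_t)(sz * Y + sy) * X;
          const int x0 = (dx < 0) ? -dx : 0;        // first valid output x
          const int x1 = (dx > 0) ? X - dx : X;     // one past last valid
          for (int i = 0; i < x0; ++i) dst[i] = 0.0;
          for (int i = x0; i < x1; ++i) dst[i] = row[i + dx];
          for (int i = x1; i < X; ++i) dst[i] = 0.0;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3_cpp(NumericMatrix g, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  NumericVector out((R_xlen_t)N * C);
  out.attr("dim") = dims;
  double *po = out.begin();
  const double *pg = g.begin();
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    for (int c = 0; c < C; ++c) {
      const double *col = pg + ((R_xlen_t)(o * C + c)) * N;
      double *dst0 = po + (R_xlen_t)c * N;
      for (int z = 0; z < Z; ++z) {
        const int sz = z + dz;
        if (sz < 0 || sz >= Z) continue;
        for (int y = 0; y < Y; ++y) {
          const int sy = y + dy;
          if (sy < 0 || sy >= Y) continue;
          const double *src = col + (R_xlen_t)(z * Y + y) * X;
          double *dst = dst0 + (R_xlen_t)(sz * Y + sy) * X;
          const int x0 = (dx < 0) ? -dx : 0;
          const int x1 = (dx > 0) ? X - dx : X;
          for (int i = x0; i < x1; ++i) dst[i + dx] += src[i];
        }
      }
    }
  }
  return out;
}
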