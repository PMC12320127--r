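#include <Rcpp.h>
using namespace Rcpp;

// Patch gather (im2col) for batched single-image columns.
// X: (npix x N) images as columns; g: gather index of length kkc*P with
// sentinel npix+1 for zero-padding taps; returns (kkc x P*N).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& X, const IntegerVector& g,
                         const int kkc) {
  const int npix = X.nrow(), N = X.ncol();
  const R_xlen_t L = g.size();
  const int P = L / kkc;
  NumericMatrix out(kkc, (R_xlen_t)P * N);
  const double* xp = REAL(X);
  double* op = REAL(out);
  const int* gp = INTEGER(g);
  for (int n = 0; n < N; ++n) {
    const double* xcol = xp + (size_t)n * npix;
    double* ocol = op + (size_t)n * P * kkc;
    for (R_xlen_t i = 0; i < L; ++i) {
      const int gi = gp[i];
      ocol[i] = (gi <= npix) ? xcol[gi - 1] : 0.0;
    }
  }
  return out;
}

// Transpose of im2col: scatter-add patch gradients back onto the images.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& dPP, const IntegerVector& g,
                         const int npix) {
  const int kkc = dPP.nrow();
  const R_xlen_t L = g.size();
  const int P = L / kkc;
  const int N = dPP.ncol() / P;
  NumericMatrix out(npix, N);
  const double* dp = REAL(dPP);
  double* op = REAL(out);
  const int* gp = INTEGER(g);
  for (int n = 0; n < N; ++n) {
    const double* dcol = dp + (size_t)n * P * kkc;
    double* ocol = op + (size_t)n * npix;
    for (R_xlen_t i = 0; i < L; ++i) {
      const int gi = gp[i];
      if (gi <= npix) ocol[gi - 1] += dcol[i];
    }
  }
  return out;
}

// Layout change (C x P*N) -> (P*C x N): channel-fastest to pixel-fastest.
// [[Rcpp::export]]
NumericMatrix chw_to_hwc_cpp(const NumericMatrix& Z, const int C,
                             const int P) {
  const int N = Z.ncol() / P;
  NumericMatrix out((R_xlen_t)P * C, N);
  const double* zp = REAL(Z);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* zi = zp + (size_t)n * P * C;
    double* oi = op + (size_t)n * P * C;
    for (int o = 0; o < P; ++o)
      for (int c = 0; c < C; ++c)
        oi[o + (size_t)c * P] = zi[c + (size_t)o * C];
  }
  return out;
}

// Inverse layout change (P*C x N) -> (C x P*N).
// [[Rcpp::export]]
NumericMatrix hwc_to_chw_cpp(const NumericMatrix& Y, const int C,
                             const int P) {
  const int N = Y.ncol();
  NumericMatrix out(C, (R_xlen_t)P * N);
  const double* yp = REAL(Y);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n) {
    const double* yi = yp + (size_t)n * P * C;
    double* oi = op + (size_t)n * P * C;
    for (int o = 0; o < P; ++o)
      for (int c = 0; c < C; ++c)
        oi[c + (size_t)o * C] = yi[o + (size_t)c * P];
  }
  return out;
}

// Window average pooling. X: (npix x M) channel-images as columns;
// g: (win^2 x P) tap indices with sentinel npix+1; n_in: in-image tap
// counts per window. Returns (P x M).
// [[Rcpp::export]]
NumericMatrix pool_fwd_cpp(const NumericMatrix& X, const IntegerMatrix& g,
                           const NumericVector& n_in) {
  const int npix = X.nrow(), M = X.ncol();
  const int T = g.nrow(), P = g.ncol();
  NumericMatrix out(P, M);
  const double* xp = REAL(X);
  double* op = REAL(out);
  const int* gp = INTEGER(g);
  for (int m = 0; m < M; ++m) {
    const double* xc = xp + (size_t)m * npix;
    double* oc = op + (size_t)m * P;
    for (int p = 0; p < P; ++p) {
      double acc = 0.0;
      const int* gt = gp + (size_t)p * T;
      for (int t = 0; t < T; ++t) {
        const int gi = gt[t];
        if (gi <= npix) acc += xc[gi - 1];
      }
      oc[p] = acc / n_in[p];
    }
  }
  return out;
}

// Transpose of pool_fwd_cpp (windows are non-overlapping).
// [[Rcpp::export]]
NumericMatrix pool_bwd_cpp(const NumericMatrix& dY, const IntegerMatrix& g,
                           const NumericVector& n_in, const int npix) {
  const int P = dY.nrow(), M = dY.ncol();
  const int T = g.nrow();
  NumericMatrix out(npix, M);
  const double* dp = REAL(dY);
  double* op = REAL(out);
  const int* gp = INTEGER(g);
  for (int m = 0; m < M; ++m) {
    const double* dc = dp + (size_t)m * P;
    double* oc = op + (size_t)m * npix;
    for (int p = 0; p < P; ++p) {
      const double v = dc[p] / n_in[p];
      const int* gt = gp + (size_t)p * T;
      for (int t = 0; t < T; ++t) {
        const int gi = gt[t];
        if (gi <= npix) oc[gi - 1] += v;
      }
    }
  }
  return out;
}
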