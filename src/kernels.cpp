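// Numeric kernels for the autodiff engine: batched GEMM over cube slices,
// gather/scatter for index-based reshuffles (window partition, im2col,
// cyclic shift), and the bilinear warp used by the resampling operator.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batched matrix multiply: slice i of the result is op(A_i) * op(B_i).
// A: (ra, ca, n), B: (rb, cb, n) as R arrays (column-major per slice).
// [[Rcpp::export]]
arma::cube bmm_cpp(const arma::cube& A, const arma::cube& B,
                   bool transA, bool transB) {
  const arma::uword n = A.n_slices;
  if (B.n_slices != n) stop("bmm: slice count mismatch");
  const arma::uword m = transA ? A.n_cols : A.n_rows;
  const arma::uword k = transA ? A.n_rows : A.n_cols;
  const arma::uword kb = transB ? B.n_cols : B.n_rows;
  const arma::uword p = transB ? B.n_rows : B.n_cols;
  if (k != kb) stop("bmm: inner dimension mismatch");
  arma::cube C(m, p, n);
  for (arma::uword i = 0; i < n; ++i) {
    if (!transA && !transB)      C.slice(i) = A.slice(i) * B.slice(i);
    else if (transA && !transB)  C.slice(i) = A.slice(i).t() * B.slice(i);
    else if (!transA && transB)  C.slice(i) = A.slice(i) * B.slice(i).t();
    else                         C.slice(i) = A.slice(i).t() * B.slice(i).t();
  }
  return C;
}

// Gather with implicit zero padding: idx is 1-based into x, 0 yields 0.0.
// [[Rcpp::export]]
NumericVector gather_pad_cpp(const NumericVector& x, const IntegerVector& idx) {
  const R_xlen_t n = idx.size();
  NumericVector out(n);
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int j = idx[i];
    out[i] = (j == 0) ? 0.0 : xp[j - 1];
  }
  return out;
}

// Adjoint of gather_pad: accumulate g into a zero vector of length n at idx.
// [[Rcpp::export]]
NumericVector scatter_add_cpp(const IntegerVector& idx, const NumericVector& g,
                              R_xlen_t n) {
  NumericVector out(n); // zero-initialized
  const R_xlen_t m = idx.size();
  if (g.size() != m) stop("scatter_add: length mismatch");
  for (R_xlen_t i = 0; i < m; ++i) {
    const int j = idx[i];
    if (j != 0) out[j - 1] += g[i];
  }
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear warp with border clamping.
// img: (C, H, W, B), flow: (2, H, W, B) in pixel units (d_row, d_col).
// out(c, r, s, b) = bilinear sample of img(c, ., ., b) at (r + dr, s + dc).
// [[Rcpp::export]]
NumericVector warp_fwd_cpp(const NumericVector& img, const NumericVector& flow,
                           int C, int H, int W, int B) {
  NumericVector out(img.size());
  const double* ip = img.begin();
  const double* fp = flow.begin();
  double* op = out.begin();
  const R_xlen_t hw2 = (R_xlen_t)2 * H * W;
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < W; ++s) {
      for (int r = 0; r < H; ++r) {
        const R_xlen_t fi = (R_xlen_t)b * hw2 + ((R_xlen_t)s * H + r) * 2;
        double rr = clampd(r + fp[fi],     0.0, H - 1.0);
        double cc = clampd(s + fp[fi + 1], 0.0, W - 1.0);
        int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
        int r1 = r0 + 1 < H ? r0 + 1 : H - 1;
        int c1 = c0 + 1 < W ? c0 + 1 : W - 1;
        double wr = rr - r0, wc = cc - c0;
        for (int c = 0; c < C; ++c) {
          // img index (c, r, s, b) -> c + C*(r + H*(s + W*b))
          const double i00 = ip[(R_xlen_t)c + (R_xlen_t)C * (r0 + (R_xlen_t)H * ((R_xlen_t)c0 + (R_xlen_t)W * b))];
          const double i10 = ip[(R_xlen_t)c + (R_xlen_t)C * (r1 + (R_xlen_t)H * ((R_xlen_t)c0 + (R_xlen_t)W * b))];
          const double i01 = ip[(R_xlen_t)c + (R_xlen_t)C * (r0 + (R_xlen_t)H * ((R_xlen_t)c1 + (R_xlen_t)W * b))];
          const double i11 = ip[(R_xlen_t)c + (R_xlen_t)C * (r1 + (R_xlen_t)H * ((R_xlen_t)c1 + (R_xlen_t)W * b))];
          op[(R_xlen_t)c + (R_xlen_t)C * (r + (R_xlen_t)H * ((R_xlen_t)s + (R_xlen_t)W * b))] =
            (1 - wr) * (1 - wc) * i00 + wr * (1 - wc) * i10 +
            (1 - wr) * wc * i01 + wr * wc * i11;
        }
      }
    }
  }
  return out;
}

// Backward of warp_fwd: returns list(gimg, gflow). Clamped coordinates have
// zero gradient with respect to the flow (derivative of clamp outside range).
// [[Rcpp::export]]
List warp_bwd_cpp(const NumericVector& img, const NumericVector& flow,
                  const NumericVector& gout, int C, int H, int W, int B) {
  NumericVector gimg(img.size());
  NumericVector gflow(flow.size());
  const double* ip = img.begin();
  const double* fp = flow.begin();
  const double* gp = gout.begin();
  double* gi = gimg.begin();
  double* gf = gflow.begin();
  const R_xlen_t hw2 = (R_xlen_t)2 * H * W;
  for (int b = 0; b < B; ++b) {
    for (int s = 0; s < W; ++s) {
      for (int r = 0; r < H; ++r) {
        const R_xlen_t fi = (R_xlen_t)b * hw2 + ((R_xlen_t)s * H + r) * 2;
        double rraw = r + fp[fi], craw = s + fp[fi + 1];
        bool rcl = (rraw < 0.0) || (rraw > H - 1.0);
        bool ccl = (craw < 0.0) || (craw > W - 1.0);
        double rr = clampd(rraw, 0.0, H - 1.0);
        double cc = clampd(craw, 0.0, W - 1.0);
        int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
        int r1 = r0 + 1 < H ? r0 + 1 : H - 1;
        int c1 = c0 + 1 < W ? c0 + 1 : W - 1;
        double wr = rr - r0, wc = cc - c0;
        double gr = 0.0, gc = 0.0;
        for (int c = 0; c < C; ++c) {
          const R_xlen_t o00 = (R_xlen_t)c + (R_xlen_t)C * (r0 + (R_xlen_t)H * ((R_xlen_t)c0 + (R_xlen_t)W * b));
          const R_xlen_t o10 = (R_xlen_t)c + (R_xlen_t)C * (r1 + (R_xlen_t)H * ((R_xlen_t)c0 + (R_xlen_t)W * b));
          const R_xlen_t o01 = (R_xlen_t)c + (R_xlen_t)C * (r0 + (R_xlen_t)H * ((R_xlen_t)c1 + (R_xlen_t)W * b));
          const R_xlen_t o11 = (R_xlen_t)c + (R_xlen_t)C * (r1 + (R_xlen_t)H * ((R_xlen_t)c1 + (R_xlen_t)W * b));
          const double g = gp[(R_xlen_t)c + (R_xlen_t)C * (r + (R_xlen_t)H * ((R_xlen_t)s + (R_xlen_t)W * b))];
          gi[o00] += g * (1 - wr) * (1 - wc);
          gi[o10] += g * wr * (1 - wc);
          gi[o01] += g * (1 - wr) * wc;
          gi[o11] += g * wr * wc;
          const double i00 = ip[o00], i10 = ip[o10], i01 = ip[o01], i11 = ip[o11];
          gr += g * ((1 - wc) * (i10 - i00) + wc * (i11 - i01));
          gc += g * ((1 - wr) * (i01 - i00) + wr * (i11 - i10));
        }
        if (!rcl) gf[fi]     += gr;
        if (!ccl) gf[fi + 1] += gc;
      }
    }
  }
  return List::create(_["gimg"] = gimg, _["gflow"] = gflow);
}

// Column-wise stabilized softmax of a (k, N) matrix.
// [[Rcpp::export]]
NumericMatrix softmax1_cpp(const NumericMatrix& X) {
  const int k = X.nrow(), N = X.ncol();
  NumericMatrix P(k, N);
  for (int j = 0; j < N; ++j) {
    const double* x = &X(0, j);
    double* p = &P(0, j);
    double mx = x[0];
    for (int i = 1; i < k; ++i) if (x[i] > mx) mx = x[i];
    double s = 0.0;
    for (int i = 0; i < k; ++i) { p[i] = std::exp(x[i] - mx); s += p[i]; }
    const double inv = 1.0 / s;
    for (int i = 0; i < k; ++i) p[i] *= inv;
  }
  return P;
}

// Backward of column-wise softmax: dX = P * (G - colsum(P * G)).
// [[Rcpp::export]]
NumericMatrix softmax1_bwd_cpp(const NumericMatrix& P,
                               const NumericMatrix& G) {
  const int k = P.nrow(), N = P.ncol();
  NumericMatrix D(k, N);
  for (int j = 0; j < N; ++j) {
    const double* p = &P(0, j);
    const double* g = &G(0, j);
    double* d = &D(0, j);
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += p[i] * g[i];
    for (int i = 0; i < k; ++i) d[i] = p[i] * (g[i] - s);
  }
  return D;
}
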