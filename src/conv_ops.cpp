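#include <Rcpp.h>
using namespace Rcpp;

// Layout conventions (column-major, matching R arrays):
//   1-D feature maps: dim (B, C, L)
//   2-D feature maps: dim (B, C, H, W)
// im2col_1d returns the patch matrix M of dim (B*Lout, C*k) with
//   row r = b + B*(t-1), col c = ci + C*(m-1),
// so conv forward is the single GEMM  M %*% W  with W of dim (C*k, Cout).
// col2im_1d scatters such a matrix back (accumulating), which is the
// transpose operation needed for the input gradient.

// [[Rcpp::export]]
NumericMatrix im2col_1d(NumericVector x, int B, int C, int L,
                        int k, int stride, int pad, int Lout) {
  NumericMatrix M(B * Lout, C * k);
  double *xm = REAL(x);
  double *out = REAL(M);
  R_xlen_t nrow = (R_xlen_t)B * Lout;
  for (int m = 0; m < k; ++m) {
    for (int ci = 0; ci < C; ++ci) {
      R_xlen_t colbase = ((R_xlen_t)(ci + C * m)) * nrow;
      for (int t = 0; t < Lout; ++t) {
        int pos = t * stride + m - pad;   // 0-based input position
        R_xlen_t rowbase = (R_xlen_t)B * t;
        if (pos < 0 || pos >= L) continue; // zeros already
        R_xlen_t inbase = (R_xlen_t)B * ci + (R_xlen_t)B * C * pos;
        for (int b = 0; b < B; ++b)
          out[colbase + rowbase + b] = xm[inbase + b];
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector col2im_1d(NumericMatrix M, int B, int C, int L,
                        int k, int stride, int pad, int Lout) {
  NumericVector x(  (R_xlen_t)B * C * L );
  double *xm = REAL(x);
  double *in = REAL(M);
  R_xlen_t nrow = (R_xlen_t)B * Lout;
  for (int m = 0; m < k; ++m) {
    for (int ci = 0; ci < C; ++ci) {
      R_xlen_t colbase = ((R_xlen_t)(ci + C * m)) * nrow;
      for (int t = 0; t < Lout; ++t) {
        int pos = t * stride + m - pad;
        if (pos < 0 || pos >= L) continue;
        R_xlen_t rowbase = (R_xlen_t)B * t;
        R_xlen_t inbase = (R_xlen_t)B * ci + (R_xlen_t)B * C * pos;
        for (int b = 0; b < B; ++b)
          xm[inbase + b] += in[colbase + rowbase + b];
      }
    }
  }
  x.attr("dim") = IntegerVector::create(B, C, L);
  return x;
}

// 2-D analogue: M has dim (B*Ho*Wo, C*kh*kw) with
//   row r = b + B*((i) + Ho*(j)), col c = ci + C*(mi + kh*mj).

// [[Rcpp::export]]
NumericMatrix im2col_2d(NumericVector x, int B, int C, int H, int W,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  NumericMatrix M = pad == 0 ?
    NumericMatrix(no_init(B * Ho * Wo, C * kh * kw)) :
    NumericMatrix(B * Ho * Wo, C * kh * kw);
  double *xm = REAL(x);
  double *out = REAL(M);
  R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  for (int mj = 0; mj < kw; ++mj) {
    for (int mi = 0; mi < kh; ++mi) {
      for (int ci = 0; ci < C; ++ci) {
        R_xlen_t colbase = ((R_xlen_t)(ci + C * (mi + kh * mj))) * nrow;
        for (int j = 0; j < Wo; ++j) {
          int pj = j * stride + mj - pad;
          if (pj < 0 || pj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            int pi = i * stride + mi - pad;
            if (pi < 0 || pi >= H) continue;
            R_xlen_t rowbase = (R_xlen_t)B * (i + (R_xlen_t)Ho * j);
            R_xlen_t inbase = (R_xlen_t)B * ci +
              (R_xlen_t)B * C * (pi + (R_xlen_t)H * pj);
            for (int b = 0; b < B; ++b)
              out[colbase + rowbase + b] = xm[inbase + b];
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector col2im_2d(NumericMatrix M, int B, int C, int H, int W,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  NumericVector x((R_xlen_t)B * C * H * W);
  double *xm = REAL(x);
  double *in = REAL(M);
  R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  for (int mj = 0; mj < kw; ++mj) {
    for (int mi = 0; mi < kh; ++mi) {
      for (int ci = 0; ci < C; ++ci) {
        R_xlen_t colbase = ((R_xlen_t)(ci + C * (mi + kh * mj))) * nrow;
        for (int j = 0; j < Wo; ++j) {
          int pj = j * stride + mj - pad;
          if (pj < 0 || pj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            int pi = i * stride + mi - pad;
            if (pi < 0 || pi >= H) continue;
            R_xlen_t rowbase = (R_xlen_t)B * (i + (R_xlen_t)Ho * j);
            R_xlen_t inbase = (R_xlen_t)B * ci +
              (R_xlen_t)B * C * (pi + (R_xlen_t)H * pj);
            for (int b = 0; b < B; ++b)
              xm[inbase + b] += in[colbase + rowbase + b];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(B, C, H, W);
  return x;
}

// Dedicated 2-D max pooling (no padding): returns the pooled values and
// 1-based argmax offsets within each k*k window, avoiding the im2col
// detour and its k^2-fold memory inflation.

// [[Rcpp::export]]
List maxpool2d_cpp(NumericVector x, int B, int C, int H, int W,
                   int k, int stride, int Ho, int Wo) {
  R_xlen_t n_out = (R_xlen_t)B * C * Ho * Wo;
  NumericVector val(no_init(n_out));
  IntegerVector arg(no_init(n_out));
  double *xm = REAL(x);
  double *vp = REAL(val);
  int *ap = INTEGER(arg);
  R_xlen_t planeBC = (R_xlen_t)B * C;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      R_xlen_t outbase = planeBC * (i + (R_xlen_t)Ho * j);
      for (R_xlen_t bc = 0; bc < planeBC; ++bc) {
        double best = R_NegInf; int besta = 1;
        for (int mj = 0; mj < k; ++mj) {
          int pj = j * stride + mj;
          for (int mi = 0; mi < k; ++mi) {
            int pi = i * stride + mi;
            double v = xm[bc + planeBC * (pi + (R_xlen_t)H * pj)];
            if (v > best) { best = v; besta = 1 + mi + k * mj; }
          }
        }
        vp[outbase + bc] = best;
        ap[outbase + bc] = besta;
      }
    }
  }
  val.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  return List::create(_["val"] = val, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(NumericVector dout, IntegerVector arg,
                                int B, int C, int H, int W,
                                int k, int stride, int Ho, int Wo) {
  NumericVector dx((R_xlen_t)B * C * H * W);
  double *dp = REAL(dout);
  double *xp = REAL(dx);
  int *ap = INTEGER(arg);
  R_xlen_t planeBC = (R_xlen_t)B * C;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      R_xlen_t outbase = planeBC * (i + (R_xlen_t)Ho * j);
      for (R_xlen_t bc = 0; bc < planeBC; ++bc) {
        int a = ap[outbase + bc] - 1;
        int mi = a % k, mj = a / k;
        int pi = i * stride + mi, pj = j * stride + mj;
        xp[bc + planeBC * (pi + (R_xlen_t)H * pj)] += dp[outbase + bc];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(B, C, H, W);
  return dx;
}
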