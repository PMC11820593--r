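// Fused convolution forward/backward with persistent workspace buffers.
//
// The im2col patch matrix, its gradient, and the GEMM output live in
// static std::vector buffers that persist across calls: they are invisible
// to R's garbage collector, whose repeated tracing of ~300 MB temporaries
// dominated training-step profiles. GEMMs go through R's own BLAS.
//
// Geometry is general (kh x kw kernels, per-axis stride/pad), so 1-D
// convolutions are the H = 1, kh = 1 special case. Optionally fuses a
// ReLU into the forward pass; the backward then masks on the cached
// output (out > 0), so no separate activation mask is stored.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
using namespace Rcpp;

// im2col workspaces are slotted so the heavy 2-D layers can keep their
// patch matrix alive between a forward pass and the matching backward
// pass within one training step (slot tag = geometry + input pointer).
#define N_SLOTS 4
static std::vector<double> w_M[N_SLOTS];
static std::vector<double> w_dM, w_Y, w_dY;
struct SlotTag {
  const double *x; int B, C, H, W, kh, kw, sh, sw, ph, pw;
  bool matches(const double *x_, int B_, int C_, int H_, int W_, int kh_,
               int kw_, int sh_, int sw_, int ph_, int pw_) const {
    return x == x_ && B == B_ && C == C_ && H == H_ && W == W_ &&
      kh == kh_ && kw == kw_ && sh == sh_ && sw == sw_ && ph == ph_ &&
      pw == pw_;
  }
};
static SlotTag slot_tag[N_SLOTS];

static void im2col_g(const double *x, int B, int C, int H, int W,
                     int kh, int kw, int sh, int sw, int ph, int pw,
                     int Ho, int Wo, double *M, bool zero_fill) {
  R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  if (zero_fill) std::fill(M, M + nrow * (R_xlen_t)C * kh * kw, 0.0);
  for (int mj = 0; mj < kw; ++mj) {
    for (int mi = 0; mi < kh; ++mi) {
      for (int ci = 0; ci < C; ++ci) {
        R_xlen_t colbase = ((R_xlen_t)(ci + C * (mi + kh * mj))) * nrow;
        for (int j = 0; j < Wo; ++j) {
          int pj = j * sw + mj - pw;
          if (pj < 0 || pj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            int pi = i * sh + mi - ph;
            if (pi < 0 || pi >= H) continue;
            R_xlen_t rowbase = (R_xlen_t)B * (i + (R_xlen_t)Ho * j);
            R_xlen_t inbase = (R_xlen_t)B * ci +
              (R_xlen_t)B * C * (pi + (R_xlen_t)H * pj);
            std::copy(x + inbase, x + inbase + B, M + colbase + rowbase);
          }
        }
      }
    }
  }
}

static void col2im_g(const double *M, int B, int C, int H, int W,
                     int kh, int kw, int sh, int sw, int ph, int pw,
                     int Ho, int Wo, double *x) {
  R_xlen_t nrow = (R_xlen_t)B * Ho * Wo;
  for (int mj = 0; mj < kw; ++mj) {
    for (int mi = 0; mi < kh; ++mi) {
      for (int ci = 0; ci < C; ++ci) {
        R_xlen_t colbase = ((R_xlen_t)(ci + C * (mi + kh * mj))) * nrow;
        for (int j = 0; j < Wo; ++j) {
          int pj = j * sw + mj - pw;
          if (pj < 0 || pj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            int pi = i * sh + mi - ph;
            if (pi < 0 || pi >= H) continue;
            R_xlen_t rowbase = (R_xlen_t)B * (i + (R_xlen_t)Ho * j);
            R_xlen_t inbase = (R_xlen_t)B * ci +
              (R_xlen_t)B * C * (pi + (R_xlen_t)H * pj);
            const double *src = M + colbase + rowbase;
            double *dst = x + inbase;
            for (int b = 0; b < B; ++b) dst[b] += src[b];
          }
        }
      }
    }
  }
}

static void gemm(const char *ta, const char *tb, int m, int n, int k,
                 const double *A, int lda, const double *Bm, int ldb,
                 double *Cm, int ldc) {
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &one, A, &lda, Bm, &ldb, &zero,
                  Cm, &ldc FCONE FCONE);
}

// [[Rcpp::export]]
NumericVector conv_fused_fwd(NumericVector x, NumericMatrix Wmat,
                             NumericVector bias, int B, int C, int H, int W,
                             int kh, int kw, int sh, int sw, int ph, int pw,
                             bool relu, int slot = 0) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  int K = C * kh * kw, Cout = Wmat.ncol();
  R_xlen_t N = (R_xlen_t)B * Ho * Wo;
  std::vector<double> &M = w_M[slot % N_SLOTS];
  M.resize(N * (R_xlen_t)K);
  w_Y.resize(N * (R_xlen_t)Cout);
  im2col_g(REAL(x), B, C, H, W, kh, kw, sh, sw, ph, pw, Ho, Wo,
           M.data(), ph > 0 || pw > 0);
  slot_tag[slot % N_SLOTS] = SlotTag{REAL(x), B, C, H, W, kh, kw, sh, sw,
                                     ph, pw};
  gemm("N", "N", (int)N, Cout, K, M.data(), (int)N, REAL(Wmat), K,
       w_Y.data(), (int)N);
  NumericVector out(no_init(N * (R_xlen_t)Cout));
  double *op = REAL(out);
  const double *bp = REAL(bias);
  // permute (b, i, j, co) -> (b, co, i, j), add bias, optional ReLU
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      for (int co = 0; co < Cout; ++co) {
        const double *src = w_Y.data() +
          (R_xlen_t)N * co + (R_xlen_t)B * (i + (R_xlen_t)Ho * j);
        double *dst = op + (R_xlen_t)B * co +
          (R_xlen_t)B * Cout * (i + (R_xlen_t)Ho * j);
        double bc = bp[co];
        if (relu) {
          for (int b = 0; b < B; ++b) {
            double v = src[b] + bc;
            dst[b] = v > 0 ? v : 0.0;
          }
        } else {
          for (int b = 0; b < B; ++b) dst[b] = src[b] + bc;
        }
      }
  out.attr("dim") = IntegerVector::create(B, Cout, Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List conv_fused_bwd(NumericVector x, NumericMatrix Wmat, NumericVector out,
                    NumericVector dout, int B, int C, int H, int W,
                    int kh, int kw, int sh, int sw, int ph, int pw,
                    bool relu, int slot = 0) {
  int Ho = (H + 2 * ph - kh) / sh + 1;
  int Wo = (W + 2 * pw - kw) / sw + 1;
  int K = C * kh * kw, Cout = Wmat.ncol();
  R_xlen_t N = (R_xlen_t)B * Ho * Wo;
  std::vector<double> &M = w_M[slot % N_SLOTS];
  w_dY.resize(N * (R_xlen_t)Cout);
  w_dM.resize(N * (R_xlen_t)K);
  bool have_M = (R_xlen_t)M.size() == N * (R_xlen_t)K &&
    slot_tag[slot % N_SLOTS].matches(REAL(x), B, C, H, W, kh, kw, sh, sw,
                                     ph, pw);
  if (!have_M) {
    M.resize(N * (R_xlen_t)K);
    im2col_g(REAL(x), B, C, H, W, kh, kw, sh, sw, ph, pw, Ho, Wo,
             M.data(), ph > 0 || pw > 0);
  }
  const double *dp = REAL(dout), *op = REAL(out);
  NumericVector db(Cout);
  double *dbp = REAL(db);
  // permute dout (b, co, i, j) -> dY (b, i, j, co); ReLU mask from out
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      for (int co = 0; co < Cout; ++co) {
        R_xlen_t src_off = (R_xlen_t)B * co +
          (R_xlen_t)B * Cout * (i + (R_xlen_t)Ho * j);
        double *dst = w_dY.data() + (R_xlen_t)N * co +
          (R_xlen_t)B * (i + (R_xlen_t)Ho * j);
        double acc = 0.0;
        if (relu) {
          for (int b = 0; b < B; ++b) {
            double g = op[src_off + b] > 0 ? dp[src_off + b] : 0.0;
            dst[b] = g;
            acc += g;
          }
        } else {
          for (int b = 0; b < B; ++b) {
            dst[b] = dp[src_off + b];
            acc += dp[src_off + b];
          }
        }
        dbp[co] += acc;
      }
  NumericMatrix dW(K, Cout);
  gemm("T", "N", K, Cout, (int)N, M.data(), (int)N, w_dY.data(), (int)N,
       REAL(dW), K);
  gemm("N", "T", (int)N, K, Cout, w_dY.data(), (int)N, REAL(Wmat), K,
       w_dM.data(), (int)N);
  NumericVector dx((R_xlen_t)B * C * H * W);
  col2im_g(w_dM.data(), B, C, H, W, kh, kw, sh, sw, ph, pw, Ho, Wo,
           REAL(dx));
  dx.attr("dim") = IntegerVector::create(B, C, H, W);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// release the persistent workspaces (called when a session wants memory back)
// [[Rcpp::export]]
void conv_workspace_release() {
  for (int i = 0; i < N_SLOTS; ++i) {
    std::vector<double>().swap(w_M[i]);
    slot_tag[i] = SlotTag{};
  }
  std::vector<double>().swap(w_dM);
  std::vector<double>().swap(w_Y);
  std::vector<double>().swap(w_dY);
}
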