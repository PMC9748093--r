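// Multiscale CNN-BiLSTM backbone: forward, backprop and SGD-momentum
// training, written directly against BLAS via Armadillo. The network is
// templated on the element type: float for training speed, double for the
// finite-difference gradient-check path used by the test suite.
//
// Architecture (fixed topology, sizes configurable):
//   input L x 1
//   -> two parallel 1-D conv branches (kernel sizes bK, bF filters each),
//      each conv + batch-norm + ELU, outputs concatenated channel-wise
//   -> n trunk stages: conv (kernel tK, tF filters, stride 1, SAME)
//      + batch-norm + ELU + average pooling (window pools[s], VALID)
//      + dropout(p_conv)
//   -> BiLSTM over the pooled sequence (H units per direction, concat 2H)
//   -> residual add of the conv path and the BiLSTM output
//   -> flatten -> fully connected (fc units) + ELU + dropout(p_fc)
//   -> 1-unit sigmoid head (stage-1 training)
//
// Memory layout: batch activations live in one column-major matrix of
// (G + B * (len + G)) rows x C columns — each record occupies a contiguous
// block of `len` rows separated by G zero "gap" rows. The zero gaps double
// as the SAME-padding halo, so every convolution tap is a single strided
// GEMM over the whole batch. Invariant maintained throughout: any matrix
// used as a GEMM *input* has all-zero gap rows; garbage written into gap
// rows of GEMM outputs is never read (all element-wise ops are block-wise
// or zero-preserving).

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Direct strided GEMM so row-blocks of column-major matrices feed BLAS
// without the temporary copies an Armadillo subview multiplication makes.
extern "C" {
void sgemm_(const char*, const char*, const int*, const int*, const int*,
            const float*, const float*, const int*, const float*, const int*,
            const float*, float*, const int*);
void dgemm_(const char*, const char*, const int*, const int*, const int*,
            const double*, const double*, const int*, const double*, const int*,
            const double*, double*, const int*);
}

template <typename eT>
static inline void blas_gemm(char ta, char tb, int m, int n, int k, eT alpha,
                             const eT* A, int lda, const eT* B, int ldb,
                             eT beta, eT* C, int ldc);

template <>
inline void blas_gemm<float>(char ta, char tb, int m, int n, int k, float alpha,
                             const float* A, int lda, const float* B, int ldb,
                             float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

template <>
inline void blas_gemm<double>(char ta, char tb, int m, int n, int k, double alpha,
                              const double* A, int lda, const double* B, int ldb,
                              double beta, double* C, int ldc) {
  dgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct Cfg {
  int L;
  std::vector<int> bK;
  int bF;
  int tK, tF;
  std::vector<int> pools;
  double p_conv;
  int H;
  int fc;
  double p_fc;
  // derived
  int C0;                 // channels after branch concat
  std::vector<int> lens;  // sequence length after each pooling stage
  int Tf, flat;
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.L = as<int>(cfg["input_length"]);
  c.bK = as<std::vector<int>>(cfg["branch_kernels"]);
  c.bF = as<int>(cfg["branch_filters"]);
  c.tK = as<int>(cfg["trunk_kernel"]);
  c.tF = as<int>(cfg["trunk_filters"]);
  c.pools = as<std::vector<int>>(cfg["pool_windows"]);
  c.p_conv = as<double>(cfg["dropout_conv"]);
  c.H = as<int>(cfg["lstm_units"]);
  c.fc = as<int>(cfg["fc_units"]);
  c.p_fc = as<double>(cfg["dropout_fc"]);
  c.C0 = static_cast<int>(c.bK.size()) * c.bF;
  int len = c.L;
  for (size_t s = 0; s < c.pools.size(); ++s) {
    len = len / c.pools[s];
    c.lens.push_back(len);
  }
  c.Tf = len;
  c.flat = c.Tf * c.tF;
  if (2 * c.H != c.tF)
    stop("residual add requires 2 * lstm_units == trunk_filters (got %d vs %d)",
         2 * c.H, c.tF);
  if (c.Tf < 1) stop("pooling reduces the sequence below length 1");
  return c;
}

// flat batch layout: G zero rows, then B blocks of (len rows + G zero rows)
struct Flat {
  int len, B, G, stride, total;
  Flat() : len(0), B(0), G(0), stride(0), total(0) {}
  Flat(int len_, int B_, int G_)
    : len(len_), B(B_), G(G_), stride(len_ + G_), total(G_ + B_ * (len_ + G_)) {}
  inline int row0(int b) const { return G + b * stride; }
};

template <typename eT>
struct Par {
  std::vector<arma::Mat<eT>> bW;                   // per branch: K x F
  std::vector<arma::Col<eT>> bb, bg, bbe, brm, brv;
  std::vector<std::vector<arma::Mat<eT>>> tW;      // per stage, per tap: Cin x F
  std::vector<arma::Col<eT>> tb, tg, tbe, trm, trv;
  arma::Mat<eT> Wx[2], Wh[2];
  arma::Col<eT> lb[2];
  arma::Mat<eT> fcW;  arma::Col<eT> fcb;
  arma::Mat<eT> outW; arma::Col<eT> outb;
};

// visit all trainable tensors in a fixed order (BN running stats excluded)
template <typename eT, typename FM, typename FC>
static void visit_trainable(Par<eT>& p, FM fm, FC fc) {
  for (size_t i = 0; i < p.bW.size(); ++i) {
    fm(p.bW[i]); fc(p.bb[i]); fc(p.bg[i]); fc(p.bbe[i]);
  }
  for (size_t s = 0; s < p.tW.size(); ++s) {
    for (size_t k = 0; k < p.tW[s].size(); ++k) fm(p.tW[s][k]);
    fc(p.tb[s]); fc(p.tg[s]); fc(p.tbe[s]);
  }
  for (int d = 0; d < 2; ++d) { fm(p.Wx[d]); fm(p.Wh[d]); fc(p.lb[d]); }
  fm(p.fcW); fc(p.fcb); fm(p.outW); fc(p.outb);
}

template <typename eT>
static Par<eT> zeros_like(const Cfg& c) {
  Par<eT> p;
  const int nb = static_cast<int>(c.bK.size());
  for (int b = 0; b < nb; ++b) {
    p.bW.push_back(arma::Mat<eT>(c.bK[b], c.bF, arma::fill::zeros));
    p.bb.push_back(arma::Col<eT>(c.bF, arma::fill::zeros));
    p.bg.push_back(arma::Col<eT>(c.bF, arma::fill::zeros));
    p.bbe.push_back(arma::Col<eT>(c.bF, arma::fill::zeros));
    p.brm.push_back(arma::Col<eT>(c.bF, arma::fill::zeros));
    p.brv.push_back(arma::Col<eT>(c.bF, arma::fill::zeros));
  }
  for (size_t s = 0; s < c.pools.size(); ++s) {
    const int Cin = (s == 0) ? c.C0 : c.tF;
    std::vector<arma::Mat<eT>> taps;
    for (int k = 0; k < c.tK; ++k)
      taps.push_back(arma::Mat<eT>(Cin, c.tF, arma::fill::zeros));
    p.tW.push_back(taps);
    p.tb.push_back(arma::Col<eT>(c.tF, arma::fill::zeros));
    p.tg.push_back(arma::Col<eT>(c.tF, arma::fill::zeros));
    p.tbe.push_back(arma::Col<eT>(c.tF, arma::fill::zeros));
    p.trm.push_back(arma::Col<eT>(c.tF, arma::fill::zeros));
    p.trv.push_back(arma::Col<eT>(c.tF, arma::fill::zeros));
  }
  for (int d = 0; d < 2; ++d) {
    p.Wx[d] = arma::Mat<eT>(c.tF, 4 * c.H, arma::fill::zeros);
    p.Wh[d] = arma::Mat<eT>(c.H, 4 * c.H, arma::fill::zeros);
    p.lb[d] = arma::Col<eT>(4 * c.H, arma::fill::zeros);
  }
  p.fcW = arma::Mat<eT>(c.flat, c.fc, arma::fill::zeros);
  p.fcb = arma::Col<eT>(c.fc, arma::fill::zeros);
  p.outW = arma::Mat<eT>(c.fc, 1, arma::fill::zeros);
  p.outb = arma::Col<eT>(1, arma::fill::zeros);
  return p;
}

// ---- R list <-> Par transport (always double on the R side) ----------------

template <typename eT>
static List par_to_list(const Par<eT>& p, const Cfg& c) {
  List out;
  const int nb = static_cast<int>(c.bK.size());
  for (int b = 0; b < nb; ++b) {
    std::string pre = "branch" + std::to_string(b + 1) + "_";
    out[pre + "W"] = wrap(arma::conv_to<arma::mat>::from(p.bW[b]));
    out[pre + "b"] = wrap(arma::conv_to<arma::vec>::from(p.bb[b]));
    out[pre + "bn_gamma"] = wrap(arma::conv_to<arma::vec>::from(p.bg[b]));
    out[pre + "bn_beta"] = wrap(arma::conv_to<arma::vec>::from(p.bbe[b]));
    out[pre + "bn_rmean"] = wrap(arma::conv_to<arma::vec>::from(p.brm[b]));
    out[pre + "bn_rvar"] = wrap(arma::conv_to<arma::vec>::from(p.brv[b]));
  }
  for (size_t s = 0; s < c.pools.size(); ++s) {
    std::string pre = "trunk" + std::to_string(s + 1) + "_";
    const int Cin = (s == 0) ? c.C0 : c.tF;
    arma::mat W(static_cast<arma::uword>(c.tK) * Cin, c.tF);
    for (int k = 0; k < c.tK; ++k)
      W.rows(static_cast<arma::uword>(k) * Cin, static_cast<arma::uword>(k + 1) * Cin - 1) =
        arma::conv_to<arma::mat>::from(p.tW[s][k]);
    out[pre + "W"] = wrap(W);
    out[pre + "b"] = wrap(arma::conv_to<arma::vec>::from(p.tb[s]));
    out[pre + "bn_gamma"] = wrap(arma::conv_to<arma::vec>::from(p.tg[s]));
    out[pre + "bn_beta"] = wrap(arma::conv_to<arma::vec>::from(p.tbe[s]));
    out[pre + "bn_rmean"] = wrap(arma::conv_to<arma::vec>::from(p.trm[s]));
    out[pre + "bn_rvar"] = wrap(arma::conv_to<arma::vec>::from(p.trv[s]));
  }
  const char* dn[2] = {"lstm_fwd_", "lstm_bwd_"};
  for (int d = 0; d < 2; ++d) {
    std::string pre = dn[d];
    out[pre + "Wx"] = wrap(arma::conv_to<arma::mat>::from(p.Wx[d]));
    out[pre + "Wh"] = wrap(arma::conv_to<arma::mat>::from(p.Wh[d]));
    out[pre + "b"] = wrap(arma::conv_to<arma::vec>::from(p.lb[d]));
  }
  out["fc_W"] = wrap(arma::conv_to<arma::mat>::from(p.fcW));
  out["fc_b"] = wrap(arma::conv_to<arma::vec>::from(p.fcb));
  out["out_W"] = wrap(arma::conv_to<arma::mat>::from(p.outW));
  out["out_b"] = wrap(arma::conv_to<arma::vec>::from(p.outb));
  return out;
}

template <typename eT>
static Par<eT> par_from_list(const List& lst, const Cfg& c) {
  Par<eT> p = zeros_like<eT>(c);
  const int nb = static_cast<int>(c.bK.size());
  auto getm = [&](const std::string& nm) {
    return arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(lst[nm]));
  };
  auto getv = [&](const std::string& nm) {
    return arma::conv_to<arma::Col<eT>>::from(as<arma::vec>(lst[nm]));
  };
  for (int b = 0; b < nb; ++b) {
    std::string pre = "branch" + std::to_string(b + 1) + "_";
    p.bW[b] = getm(pre + "W"); p.bb[b] = getv(pre + "b");
    p.bg[b] = getv(pre + "bn_gamma"); p.bbe[b] = getv(pre + "bn_beta");
    p.brm[b] = getv(pre + "bn_rmean"); p.brv[b] = getv(pre + "bn_rvar");
  }
  for (size_t s = 0; s < c.pools.size(); ++s) {
    std::string pre = "trunk" + std::to_string(s + 1) + "_";
    const int Cin = (s == 0) ? c.C0 : c.tF;
    arma::Mat<eT> W = getm(pre + "W");
    if (static_cast<int>(W.n_rows) != c.tK * Cin || static_cast<int>(W.n_cols) != c.tF)
      stop("trunk weight %s has wrong shape", pre.c_str());
    for (int k = 0; k < c.tK; ++k)
      p.tW[s][k] = W.rows(static_cast<arma::uword>(k) * Cin,
                          static_cast<arma::uword>(k + 1) * Cin - 1);
    p.tb[s] = getv(pre + "b");
    p.tg[s] = getv(pre + "bn_gamma"); p.tbe[s] = getv(pre + "bn_beta");
    p.trm[s] = getv(pre + "bn_rmean"); p.trv[s] = getv(pre + "bn_rvar");
  }
  const char* dn[2] = {"lstm_fwd_", "lstm_bwd_"};
  for (int d = 0; d < 2; ++d) {
    std::string pre = dn[d];
    p.Wx[d] = getm(pre + "Wx"); p.Wh[d] = getm(pre + "Wh");
    p.lb[d] = getv(pre + "b");
  }
  p.fcW = getm("fc_W"); p.fcb = getv("fc_b");
  p.outW = getm("out_W"); p.outb = getv("out_b");
  return p;
}

// ---- initialisation --------------------------------------------------------

template <typename eT>
static void glorot(arma::Mat<eT>& W, double fan_in, double fan_out,
                   std::mt19937& gen) {
  const double lim = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> u(-lim, lim);
  for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = static_cast<eT>(u(gen));
}

template <typename eT>
static Par<eT> init_par(const Cfg& c, int seed) {
  std::mt19937 gen(static_cast<unsigned>(seed));
  Par<eT> p = zeros_like<eT>(c);
  const int nb = static_cast<int>(c.bK.size());
  for (int b = 0; b < nb; ++b) {
    glorot(p.bW[b], c.bK[b], static_cast<double>(c.bK[b]) * c.bF, gen);
    p.bg[b].ones(); p.brv[b].ones();
  }
  for (size_t s = 0; s < c.pools.size(); ++s) {
    const int Cin = (s == 0) ? c.C0 : c.tF;
    for (int k = 0; k < c.tK; ++k)
      glorot(p.tW[s][k], static_cast<double>(c.tK) * Cin,
             static_cast<double>(c.tK) * c.tF, gen);
    p.tg[s].ones(); p.trv[s].ones();
  }
  for (int d = 0; d < 2; ++d) {
    glorot(p.Wx[d], c.tF, 4.0 * c.H, gen);
    glorot(p.Wh[d], c.H, 4.0 * c.H, gen);
    // forget-gate bias 1 stabilises early training
    p.lb[d].subvec(c.H, 2 * c.H - 1).ones();
  }
  glorot(p.fcW, c.flat, c.fc, gen);
  glorot(p.outW, c.fc, 1, gen);
  return p;
}

// ---- layers ----------------------------------------------------------------

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.1;

// SAME-padded stride-1 1-D convolution over a flat batch matrix: one strided
// GEMM per kernel tap; the zero gap rows between record blocks provide the
// padding semantics.
// row-blocked tap loop: each ~4k-row chunk of X and Z stays cache-resident
// across all K taps, so the batch matrix streams from memory once per conv
// instead of once per tap
static const int CONV_BLOCK = 768;

template <typename eT>
static void conv_same(const arma::Mat<eT>& X, const std::vector<arma::Mat<eT>>& taps,
                      const arma::Col<eT>& b, arma::Mat<eT>& Z) {
  const int L = X.n_rows;
  const int Cin = X.n_cols;
  const int F = taps[0].n_cols;
  const int K = static_cast<int>(taps.size());
  const int padl = (K - 1) / 2;
  Z.each_row() = b.t();
  for (int r0 = 0; r0 < L; r0 += CONV_BLOCK) {
    const int r1 = std::min(L - 1, r0 + CONV_BLOCK - 1);
    for (int k = 0; k < K; ++k) {
      const int off = k - padl;
      const int t1 = std::max(r0, -off), t2 = std::min(r1, L - 1 - off);
      if (t1 > t2) continue;
      blas_gemm<eT>('N', 'N', t2 - t1 + 1, F, Cin, eT(1),
                    X.memptr() + (t1 + off), L, taps[k].memptr(), Cin,
                    eT(1), Z.memptr() + t1, L);
    }
  }
}

// gradient of conv_same: dZ must have zero gap rows so dW stays exact
template <typename eT>
static void conv_same_bwd(const arma::Mat<eT>& X, const std::vector<arma::Mat<eT>>& taps,
                          const arma::Mat<eT>& dZ,
                          std::vector<arma::Mat<eT>>& dtaps, arma::Col<eT>& db,
                          arma::Mat<eT>* dX) {
  const int L = X.n_rows;
  const int Cin = X.n_cols;
  const int F = taps[0].n_cols;
  const int K = static_cast<int>(taps.size());
  const int padl = (K - 1) / 2;
  db += arma::sum(dZ, 0).t();
  for (int r0 = 0; r0 < L; r0 += CONV_BLOCK) {
    const int r1 = std::min(L - 1, r0 + CONV_BLOCK - 1);
    for (int k = 0; k < K; ++k) {
      const int off = k - padl;
      const int t1 = std::max(r0, -off), t2 = std::min(r1, L - 1 - off);
      if (t1 > t2) continue;
      const int len = t2 - t1 + 1;
      blas_gemm<eT>('T', 'N', Cin, F, len, eT(1),
                    X.memptr() + (t1 + off), L, dZ.memptr() + t1, L,
                    eT(1), dtaps[k].memptr(), Cin);
      if (dX) {
        blas_gemm<eT>('N', 'T', len, Cin, F, eT(1),
                      dZ.memptr() + t1, L, taps[k].memptr(), Cin,
                      eT(1), dX->memptr() + (t1 + off), L);
      }
    }
  }
}

// exp approximation for the float training path (exponent-bit decomposition
// with a quadratic fraction correction; ~3e-5 relative accuracy, far below
// fp32 training noise). The double path keeps exact expm1 so the
// finite-difference gradient check sees the textbook activation.
static inline float fast_exp(float x) {
  const float z = x * 1.442695041f;
  const float zi = std::floor(z);
  const float f = z - zi;
  const float p2 = 1.0f + f * (0.6565348f + f * 0.3434652f);
  int32_t i = static_cast<int32_t>((zi + 127.0f) * 8388608.0f);
  float r;
  std::memcpy(&r, &i, 4);
  return r * p2;
}

template <typename eT>
static inline eT elu1(eT v) {
  return v > eT(0) ? v : static_cast<eT>(std::expm1(static_cast<double>(v)));
}
template <>
inline float elu1<float>(float v) {
  return v > 0.0f ? v : fast_exp(std::max(v, -87.0f)) - 1.0f;
}

// ELU over a whole matrix; elu(0) = 0 so zero gap rows stay zero
template <typename eT>
static void elu_inplace(arma::Mat<eT>& Z) {
  eT* p = Z.memptr();
  const size_t n = Z.n_elem;
  for (size_t i = 0; i < n; ++i) p[i] = elu1(p[i]);
}

template <typename eT>
static arma::Mat<eT> elu(const arma::Mat<eT>& Z) {
  arma::Mat<eT> A = Z;
  elu_inplace(A);
  return A;
}

// dA *= elu'(a); zero rows of dA stay zero regardless of a
template <typename eT>
static void elu_bwd_inplace(const arma::Mat<eT>& A, arma::Mat<eT>& dA) {
  const eT* a = A.memptr();
  eT* d = dA.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const eT m = a[i] > eT(0) ? eT(1) : a[i] + eT(1);
    d[i] *= m;
  }
}

template <typename eT>
static arma::Mat<eT> elu_bwd(const arma::Mat<eT>& A, const arma::Mat<eT>& dA) {
  arma::Mat<eT> dZ = dA;
  elu_bwd_inplace(A, dZ);
  return dZ;
}

// no-copy view of a contiguous column range
template <typename eT>
static inline arma::Mat<eT> cols_view(arma::Mat<eT>& M, int c0, int nc) {
  return arma::Mat<eT>(M.colptr(c0), M.n_rows, nc, false, true);
}

// batch norm per channel over the record blocks of a flat matrix (gap rows
// excluded from statistics and left untouched by the transform)
template <typename eT>
struct BNCache { arma::Col<eT> mu, invsd; arma::Mat<eT> xhat; };

// fuse_elu applies the ELU activation inside the normalisation pass (one
// memory sweep instead of two); gap rows stay untouched (zero)
template <typename eT>
static void bn_fwd(arma::Mat<eT>& Z, const Flat& fl, const arma::Col<eT>& g,
                   const arma::Col<eT>& be, arma::Col<eT>& rm, arma::Col<eT>& rv,
                   bool train, BNCache<eT>* cache, bool fuse_elu = false) {
  const int C = Z.n_cols;
  const int total = Z.n_rows;
  const double n = static_cast<double>(fl.len) * fl.B;
  arma::Col<eT> mu(C), var(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      // unrolled accumulators so the strict-FP sum vectorises
      double s0 = 0.0, s1 = 0.0, s2a = 0.0, s2b = 0.0;
      const eT* col = Z.colptr(c);
      for (int b = 0; b < fl.B; ++b) {
        const eT* p = col + fl.row0(b);
        int t = 0;
        for (; t + 1 < fl.len; t += 2) {
          const double v0 = static_cast<double>(p[t]);
          const double v1 = static_cast<double>(p[t + 1]);
          s0 += v0; s1 += v1;
          s2a += v0 * v0; s2b += v1 * v1;
        }
        for (; t < fl.len; ++t) {
          const double v = static_cast<double>(p[t]);
          s0 += v; s2a += v * v;
        }
      }
      const double s = s0 + s1, s2 = s2a + s2b;
      const double m = s / n;
      mu[c] = static_cast<eT>(m);
      var[c] = static_cast<eT>(std::max(0.0, s2 / n - m * m));
    }
    rm = (eT(1) - eT(BN_MOM)) * rm + eT(BN_MOM) * mu;
    rv = (eT(1) - eT(BN_MOM)) * rv + eT(BN_MOM) * var;
  } else {
    mu = rm; var = rv;
  }
  arma::Col<eT> invsd(C);
  for (int c = 0; c < C; ++c)
    invsd[c] = static_cast<eT>(1.0 / std::sqrt(static_cast<double>(var[c]) + BN_EPS));
  if (cache) {
    cache->mu = mu; cache->invsd = invsd;
    cache->xhat.set_size(total, C);  // block rows are written below;
                                     // gap rows are never read
  }
  for (int c = 0; c < C; ++c) {
    eT* col = Z.colptr(c);
    eT* xh = cache ? cache->xhat.colptr(c) : nullptr;
    const eT m = mu[c], is = invsd[c], gc = g[c], bc = be[c];
    for (int b = 0; b < fl.B; ++b) {
      eT* p = col + fl.row0(b);
      if (xh) {
        eT* xp = xh + fl.row0(b);
        if (fuse_elu) {
          for (int t = 0; t < fl.len; ++t) {
            xp[t] = (p[t] - m) * is;
            p[t] = elu1(gc * xp[t] + bc);
          }
        } else {
          for (int t = 0; t < fl.len; ++t) {
            xp[t] = (p[t] - m) * is;
            p[t] = gc * xp[t] + bc;
          }
        }
      } else if (fuse_elu) {
        for (int t = 0; t < fl.len; ++t) p[t] = elu1(gc * (p[t] - m) * is + bc);
      } else {
        for (int t = 0; t < fl.len; ++t) p[t] = gc * (p[t] - m) * is + bc;
      }
    }
  }
}

template <typename eT>
static void bn_bwd(const BNCache<eT>& cache, const Flat& fl, const arma::Col<eT>& g,
                   arma::Mat<eT>& dY, arma::Col<eT>& dg, arma::Col<eT>& dbe,
                   const arma::Mat<eT>* elu_act = nullptr) {
  // dY is overwritten with dX (block rows only; gap rows remain zero).
  // When elu_act is given, dY is first multiplied by elu'(a) in the same
  // pass (the fused ELU backward).
  const int C = dY.n_cols;
  const double n = static_cast<double>(fl.len) * fl.B;
  for (int c = 0; c < C; ++c) {
    double a0 = 0.0, a1 = 0.0, b0 = 0.0, b1 = 0.0;
    eT* dyc = dY.colptr(c);
    const eT* xhc = cache.xhat.colptr(c);
    const eT* ac = elu_act ? elu_act->colptr(c) : nullptr;
    for (int b = 0; b < fl.B; ++b) {
      eT* dy = dyc + fl.row0(b);
      const eT* xh = xhc + fl.row0(b);
      if (ac) {
        const eT* a = ac + fl.row0(b);
        for (int t = 0; t < fl.len; ++t) {
          const eT mlt = a[t] > eT(0) ? eT(1) : a[t] + eT(1);
          dy[t] *= mlt;
        }
      }
      int t = 0;
      for (; t + 1 < fl.len; t += 2) {
        a0 += static_cast<double>(dy[t]);
        a1 += static_cast<double>(dy[t + 1]);
        b0 += static_cast<double>(dy[t]) * xh[t];
        b1 += static_cast<double>(dy[t + 1]) * xh[t + 1];
      }
      for (; t < fl.len; ++t) {
        a0 += static_cast<double>(dy[t]);
        b0 += static_cast<double>(dy[t]) * xh[t];
      }
    }
    const double sum_dy = a0 + a1, sum_dy_xh = b0 + b1;
    dg[c] += static_cast<eT>(sum_dy_xh);
    dbe[c] += static_cast<eT>(sum_dy);
    const eT k1 = static_cast<eT>(sum_dy / n);
    const eT k2 = static_cast<eT>(sum_dy_xh / n);
    const eT gi = g[c] * cache.invsd[c];
    for (int b = 0; b < fl.B; ++b) {
      eT* dy = dyc + fl.row0(b);
      const eT* xh = xhc + fl.row0(b);
      for (int t = 0; t < fl.len; ++t) dy[t] = gi * (dy[t] - k1 - xh[t] * k2);
    }
  }
}

// valid-padding average pooling between two flat layouts
template <typename eT>
static void avgpool(const arma::Mat<eT>& X, const Flat& fin,
                    arma::Mat<eT>& Y, const Flat& fout, int w) {
  const int C = X.n_cols;
  const eT inv = eT(1) / static_cast<eT>(w);
  for (int c = 0; c < C; ++c) {
    const eT* xc = X.colptr(c);
    eT* yc = Y.colptr(c);
    for (int b = 0; b < fin.B; ++b) {
      const eT* in = xc + fin.row0(b);
      eT* out = yc + fout.row0(b);
      for (int t = 0; t < fout.len; ++t) {
        eT s = eT(0);
        const eT* p = in + static_cast<size_t>(t) * w;
        for (int j = 0; j < w; ++j) s += p[j];
        out[t] = s * inv;
      }
    }
  }
}

template <typename eT>
static void avgpool_bwd(const arma::Mat<eT>& dY, const Flat& fout,
                        arma::Mat<eT>& dX, const Flat& fin, int w) {
  const int C = dY.n_cols;
  const eT inv = eT(1) / static_cast<eT>(w);
  for (int c = 0; c < C; ++c) {
    const eT* dyc = dY.colptr(c);
    eT* dxc = dX.colptr(c);
    for (int b = 0; b < fout.B; ++b) {
      const eT* dy = dyc + fout.row0(b);
      eT* dx = dxc + fin.row0(b);
      for (int t = 0; t < fout.len; ++t) {
        const eT v = dy[t] * inv;
        eT* p = dx + static_cast<size_t>(t) * w;
        for (int j = 0; j < w; ++j) p[j] = v;
      }
    }
  }
}

// inverted dropout on the record blocks; mask has zero gap rows so a full
// element-wise product also re-zeroes any gap garbage
template <typename eT>
static void dropout_fwd(arma::Mat<eT>& X, arma::Mat<eT>& mask, const Flat& fl,
                        double p, bool train, std::mt19937& gen) {
  mask.zeros(X.n_rows, X.n_cols);
  const int C = X.n_cols;
  if (train && p > 0) {
    const eT inv_keep = static_cast<eT>(1.0 / (1.0 - p));
    const uint32_t thr = static_cast<uint32_t>(p * 4294967296.0);
    for (int c = 0; c < C; ++c) {
      eT* mc = mask.colptr(c);
      for (int b = 0; b < fl.B; ++b) {
        eT* m = mc + fl.row0(b);
        for (int t = 0; t < fl.len; ++t)
          m[t] = (static_cast<uint32_t>(gen()) < thr) ? eT(0) : inv_keep;
      }
    }
    X %= mask;
  } else {
    for (int c = 0; c < C; ++c) {
      eT* mc = mask.colptr(c);
      for (int b = 0; b < fl.B; ++b)
        std::fill(mc + fl.row0(b), mc + fl.row0(b) + fl.len, eT(1));
    }
  }
}

// ---- LSTM ------------------------------------------------------------------

template <typename eT>
struct LSTMCache {
  std::vector<arma::Mat<eT>> I, F, G, O, Cc, TC, Hprev, Cprev, Xt;
};

template <typename eT>
static arma::Mat<eT> sigm(arma::Mat<eT> Z) {
  Z.transform([](eT v) { return static_cast<eT>(1.0 / (1.0 + std::exp(-static_cast<double>(v)))); });
  return Z;
}

// run one direction; Xt[t] are B x C inputs in original time order; order
// gives the processing sequence. Output: per original timestep h (B x H).
template <typename eT>
static std::vector<arma::Mat<eT>> lstm_fwd(const std::vector<arma::Mat<eT>>& Xt,
                                           const std::vector<int>& order,
                                           const arma::Mat<eT>& Wx, const arma::Mat<eT>& Wh,
                                           const arma::Col<eT>& b, int H,
                                           LSTMCache<eT>* cache) {
  const int T = static_cast<int>(Xt.size());
  const int B = Xt[0].n_rows;
  std::vector<arma::Mat<eT>> Hs(T);
  arma::Mat<eT> h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  if (cache) {
    cache->I.resize(T); cache->F.resize(T); cache->G.resize(T); cache->O.resize(T);
    cache->Cc.resize(T); cache->TC.resize(T); cache->Hprev.resize(T);
    cache->Cprev.resize(T); cache->Xt.resize(T);
  }
  for (int s = 0; s < T; ++s) {
    const int t = order[s];
    arma::Mat<eT> Z = Xt[t] * Wx + h * Wh;
    Z.each_row() += b.t();
    arma::Mat<eT> I = sigm(arma::Mat<eT>(Z.cols(0, H - 1)));
    arma::Mat<eT> F = sigm(arma::Mat<eT>(Z.cols(H, 2 * H - 1)));
    arma::Mat<eT> G = arma::tanh(Z.cols(2 * H, 3 * H - 1));
    arma::Mat<eT> O = sigm(arma::Mat<eT>(Z.cols(3 * H, 4 * H - 1)));
    arma::Mat<eT> cprev = c, hprev = h;
    c = F % c + I % G;
    arma::Mat<eT> tc = arma::tanh(c);
    h = O % tc;
    if (cache) {
      cache->I[t] = I; cache->F[t] = F; cache->G[t] = G; cache->O[t] = O;
      cache->Cc[t] = c; cache->TC[t] = tc; cache->Hprev[t] = hprev;
      cache->Cprev[t] = cprev; cache->Xt[t] = Xt[t];
    }
    Hs[t] = h;
  }
  return Hs;
}

template <typename eT>
static void lstm_bwd(const LSTMCache<eT>& cache, const std::vector<int>& order,
                     const arma::Mat<eT>& Wx, const arma::Mat<eT>& Wh,
                     const std::vector<arma::Mat<eT>>& dHs,
                     arma::Mat<eT>& dWx, arma::Mat<eT>& dWh, arma::Col<eT>& db,
                     std::vector<arma::Mat<eT>>& dXt) {
  const int T = static_cast<int>(order.size());
  const int H = Wh.n_rows;
  const int B = dHs[order[0]].n_rows;
  arma::Mat<eT> dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    const int t = order[s];
    arma::Mat<eT> dh = dHs[t] + dh_next;
    arma::Mat<eT> dO = dh % cache.TC[t];
    arma::Mat<eT> dc = dh % cache.O[t] % (eT(1) - cache.TC[t] % cache.TC[t]) + dc_next;
    arma::Mat<eT> dI = dc % cache.G[t];
    arma::Mat<eT> dF = dc % cache.Cprev[t];
    arma::Mat<eT> dG = dc % cache.I[t];
    arma::Mat<eT> dZ(B, 4 * H);
    dZ.cols(0, H - 1) = dI % cache.I[t] % (eT(1) - cache.I[t]);
    dZ.cols(H, 2 * H - 1) = dF % cache.F[t] % (eT(1) - cache.F[t]);
    dZ.cols(2 * H, 3 * H - 1) = dG % (eT(1) - cache.G[t] % cache.G[t]);
    dZ.cols(3 * H, 4 * H - 1) = dO % cache.O[t] % (eT(1) - cache.O[t]);
    dWx += cache.Xt[t].t() * dZ;
    dWh += cache.Hprev[t].t() * dZ;
    db += arma::sum(dZ, 0).t();
    dXt[t] += dZ * Wx.t();
    dh_next = dZ * Wh.t();
    dc_next = dc % cache.F[t];
  }
}

// ---- full network ----------------------------------------------------------

template <typename eT>
struct Cache {
  Flat fl0;                              // layout at input resolution
  std::vector<Flat> flp;                 // layout after each pooling stage
  arma::Mat<eT> X1;                      // post-branch concat (ELU out), flat
  std::vector<BNCache<eT>> bn_b;         // per branch
  std::vector<BNCache<eT>> bn_t;         // per trunk stage
  std::vector<arma::Mat<eT>> trunk_a;    // ELU out per stage (pool input)
  std::vector<arma::Mat<eT>> trunk_pool; // pooled (and dropped-out) per stage
  std::vector<arma::Mat<eT>> drop_mask;  // dropout mask per stage
  LSTMCache<eT> lstm[2];
  std::vector<arma::Mat<eT>> lstm_in;    // per timestep B x C
  arma::Mat<eT> flatF;                   // B x flat
  arma::Mat<eT> fcA;                     // ELU out B x fc
  arma::Mat<eT> fc_mask;                 // dropout mask
  arma::Mat<eT> fcD;                     // post-dropout
  arma::Col<eT> prob;                    // B
  // reusable scratch (avoids reallocating tens of MB per minibatch)
  std::vector<arma::Mat<eT>> br_xc;      // per-branch im2col buffer
  arma::Mat<eT> bw_gtop;                 // grad at last pooled output
  std::vector<arma::Mat<eT>> bw_g;       // grad at each stage input
  std::vector<arma::Mat<eT>> bw_a;       // grad at each stage pre-pool
  arma::Mat<eT> bw_dBr;                  // per-branch grad block
};

typedef std::vector<std::pair<std::string, std::string>> ShapeLog;

static std::string dim2(int a, int b) {
  return std::to_string(a) + "x" + std::to_string(b);
}

// gap between record blocks; must cover the largest trunk-conv tap offset
static const int FLAT_GAP = 32;

template <typename eT>
static void forward(const Cfg& cfg, Par<eT>& par, const arma::Mat<eT>& X,
                    bool train, std::mt19937& gen, Cache<eT>& K,
                    ShapeLog* shapes) {
  const int B = X.n_cols;
  const int nb = static_cast<int>(cfg.bK.size());
  if (shapes) shapes->push_back({"signal_input", dim2(cfg.L, 1)});

  K.fl0 = Flat(cfg.L, B, FLAT_GAP);
  const Flat& fl0 = K.fl0;

  // branches: conv (im2col per record) + BN + ELU, concatenated channel-wise
  { K.X1.zeros(fl0.total, cfg.C0); }
  if (static_cast<int>(K.bn_b.size()) != nb) {
    K.bn_b.resize(nb);
    K.br_xc.resize(nb);
  }
  for (int br = 0; br < nb; ++br) {
    const int Kk = cfg.bK[br];
    const int padl = (Kk - 1) / 2;
    // per-record im2col blocks, cached for the backward weight gradient
    arma::Mat<eT>& Xc = K.br_xc[br];
    Xc.set_size(cfg.L, static_cast<arma::uword>(Kk) * B);
    arma::Mat<eT> Zcols = cols_view(K.X1, br * cfg.bF, cfg.bF);
    for (int b = 0; b < B; ++b) {
      const eT* x = X.colptr(b);
      eT* xc0 = Xc.colptr(static_cast<arma::uword>(b) * Kk);
      for (int k = 0; k < Kk; ++k) {
        const int off = k - padl;
        const int t1 = std::max(0, -off), t2 = std::min(cfg.L - 1, cfg.L - 1 - off);
        eT* col = xc0 + static_cast<size_t>(k) * cfg.L;
        if (t1 > 0) std::fill(col, col + t1, eT(0));
        if (t2 < cfg.L - 1) std::fill(col + t2 + 1, col + cfg.L, eT(0));
        std::copy(x + t1 + off, x + t2 + off + 1, col + t1);
      }
      // write conv output (plus bias) directly into the record's block rows
      for (int f = 0; f < cfg.bF; ++f)
        std::fill(Zcols.colptr(f) + fl0.row0(b),
                  Zcols.colptr(f) + fl0.row0(b) + cfg.L, par.bb[br][f]);
      blas_gemm<eT>('N', 'N', cfg.L, cfg.bF, Kk, eT(1), xc0, cfg.L,
                    par.bW[br].memptr(), Kk, eT(1),
                    Zcols.memptr() + fl0.row0(b), fl0.total);
    }
    if (shapes) shapes->push_back({"branch_conv" + std::to_string(br + 1),
                                   dim2(cfg.L, cfg.bF)});
    // BN with fused ELU; gap rows stay untouched (zero)
    bn_fwd(Zcols, fl0, par.bg[br], par.bbe[br], par.brm[br], par.brv[br], train,
           train ? &K.bn_b[br] : nullptr, true);
  }
  if (shapes) shapes->push_back({"branch_concat", dim2(cfg.L, cfg.C0)});

  // trunk stages
  const int S = static_cast<int>(cfg.pools.size());
  if (static_cast<int>(K.bn_t.size()) != S) {
    K.bn_t.resize(S);
    K.trunk_a.resize(S);
    K.trunk_pool.resize(S);
    K.drop_mask.resize(S);
    K.bw_g.resize(S);
    K.bw_a.resize(S);
  }
  K.flp.assign(S, Flat());
  arma::Mat<eT>* cur = &K.X1;
  Flat fin = fl0;
  for (int s = 0; s < S; ++s) {
    arma::Mat<eT>& Z = K.trunk_a[s];
    Z.set_size(fin.total, cfg.tF);
    { conv_same(*cur, par.tW[s], par.tb[s], Z); }
    if (shapes) shapes->push_back({"trunk_conv" + std::to_string(s + 1),
                                   dim2(fin.len, cfg.tF)});
    bn_fwd(Z, fin, par.tg[s], par.tbe[s], par.trm[s], par.trv[s], train,
           train ? &K.bn_t[s] : nullptr, true);
    const int w = cfg.pools[s];
    const Flat fout(fin.len / w, B, FLAT_GAP);
    K.flp[s] = fout;
    K.trunk_pool[s].zeros(fout.total, cfg.tF);
    avgpool(K.trunk_a[s], fin, K.trunk_pool[s], fout, w);
    if (shapes) shapes->push_back({"avg_pool" + std::to_string(s + 1),
                                   dim2(fout.len, cfg.tF)});
    { dropout_fwd(K.trunk_pool[s], K.drop_mask[s], fout, cfg.p_conv, train, gen); }
    if (shapes) shapes->push_back({"dropout" + std::to_string(s + 1),
                                   dim2(fout.len, cfg.tF)});
    cur = &K.trunk_pool[s];
    fin = fout;
  }

  // BiLSTM over the final pooled sequence
  const int T = cfg.Tf;
  const Flat& flT = K.flp[S - 1];
  K.lstm_in.assign(T, arma::Mat<eT>(B, cfg.tF));
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < cfg.tF; ++c) {
      const eT* col = cur->colptr(c);
      eT* dst = K.lstm_in[t].colptr(c);
      for (int b = 0; b < B; ++b) dst[b] = col[flT.row0(b) + t];
    }
  std::vector<int> fwd_order(T), bwd_order(T);
  for (int t = 0; t < T; ++t) { fwd_order[t] = t; bwd_order[t] = T - 1 - t; }
  std::vector<arma::Mat<eT>> Hf = lstm_fwd(K.lstm_in, fwd_order, par.Wx[0],
                                           par.Wh[0], par.lb[0], cfg.H,
                                           train ? &K.lstm[0] : nullptr);
  std::vector<arma::Mat<eT>> Hb = lstm_fwd(K.lstm_in, bwd_order, par.Wx[1],
                                           par.Wh[1], par.lb[1], cfg.H,
                                           train ? &K.lstm[1] : nullptr);
  if (shapes) shapes->push_back({"bilstm", dim2(T, 2 * cfg.H)});

  // residual add (conv path + BiLSTM), flatten (channel-major per record)
  if (shapes) shapes->push_back({"add", dim2(T, cfg.tF)});
  K.flatF.set_size(B, cfg.flat);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < cfg.tF; ++c) {
      const eT* col = cur->colptr(c) + flT.row0(b);
      eT* dst = K.flatF.memptr();  // (B x flat), column c*T + t holds value
      for (int t = 0; t < T; ++t) {
        const eT lstm_v = (c < cfg.H) ? Hf[t](b, c) : Hb[t](b, c - cfg.H);
        dst[static_cast<size_t>(c * T + t) * B + b] = col[t] + lstm_v;
      }
    }
  }
  if (shapes) shapes->push_back({"flatten", dim2(1, cfg.flat)});

  // FC + ELU + dropout + sigmoid head
  arma::Mat<eT> Zfc = K.flatF * par.fcW;
  Zfc.each_row() += par.fcb.t();
  K.fcA = elu(Zfc);
  if (shapes) shapes->push_back({"fully_connected", dim2(1, cfg.fc)});
  K.fc_mask.set_size(B, cfg.fc);
  if (train && cfg.p_fc > 0) {
    const eT inv_keep = static_cast<eT>(1.0 / (1.0 - cfg.p_fc));
    const uint32_t thr = static_cast<uint32_t>(cfg.p_fc * 4294967296.0);
    for (arma::uword i = 0; i < K.fc_mask.n_elem; ++i)
      K.fc_mask[i] = (static_cast<uint32_t>(gen()) < thr) ? eT(0) : inv_keep;
  } else {
    K.fc_mask.ones();
  }
  K.fcD = K.fcA % K.fc_mask;
  if (shapes) shapes->push_back({"fc_dropout", dim2(1, cfg.fc)});
  arma::Mat<eT> logit = K.fcD * par.outW;
  logit.each_row() += par.outb.t();
  K.prob = sigm(logit).col(0);
  if (shapes) {
    shapes->push_back({"head_fc", "1x1"});
    shapes->push_back({"sigmoid", "1x1"});
  }
}

// weighted binary cross-entropy; y in {0,1}, w per-class weights (w0 normal,
// w1 pathological); returns mean loss and writes dlogit
template <typename eT>
static double wbce(const arma::Col<eT>& prob, const arma::ivec& y,
                   const arma::vec& cw, arma::Col<eT>* dlogit) {
  const int B = prob.n_elem;
  double loss = 0.0;
  if (dlogit) dlogit->set_size(B);
  const double eps = 1e-7;
  for (int i = 0; i < B; ++i) {
    double p = std::min(1.0 - eps, std::max(eps, static_cast<double>(prob[i])));
    const double w = y[i] == 1 ? cw[1] : cw[0];
    loss += -w * (y[i] * std::log(p) + (1 - y[i]) * std::log(1.0 - p));
    if (dlogit) (*dlogit)[i] = static_cast<eT>(w * (p - y[i]) / B);
  }
  return loss / B;
}

template <typename eT>
static void backward(const Cfg& cfg, Par<eT>& par, const arma::Mat<eT>& X,
                     Cache<eT>& K, const arma::Col<eT>& dlogit, Par<eT>& g) {
  const int B = X.n_cols;
  const int T = cfg.Tf;
  const int S = static_cast<int>(cfg.pools.size());
  const int nb = static_cast<int>(cfg.bK.size());
  const Flat& fl0 = K.fl0;

  // head
  g.outW += K.fcD.t() * dlogit;
  g.outb[0] += arma::accu(dlogit);
  arma::Mat<eT> dD = dlogit * par.outW.t();       // B x fc
  arma::Mat<eT> dA = dD % K.fc_mask;
  arma::Mat<eT> dZfc = elu_bwd(K.fcA, dA);
  g.fcW += K.flatF.t() * dZfc;
  g.fcb += arma::sum(dZfc, 0).t();
  arma::Mat<eT> dF = dZfc * par.fcW.t();          // B x flat

  // unflatten -> residual add: gradient splits to the conv path (flat) and
  // the per-timestep BiLSTM outputs
  const Flat& flT = K.flp[S - 1];
  K.bw_gtop.zeros(flT.total, cfg.tF);
  arma::Mat<eT>& dPool = K.bw_gtop;
  std::vector<arma::Mat<eT>> dHf(T, arma::Mat<eT>(B, cfg.H)),
                             dHb(T, arma::Mat<eT>(B, cfg.H));
  for (int c = 0; c < cfg.tF; ++c) {
    eT* dcol = dPool.colptr(c);
    const eT* src = dF.memptr();
    for (int b = 0; b < B; ++b) {
      eT* dp = dcol + flT.row0(b);
      for (int t = 0; t < T; ++t) {
        const eT v = src[static_cast<size_t>(c * T + t) * B + b];
        dp[t] = v;
        if (c < cfg.H) dHf[t](b, c) = v; else dHb[t](b, c - cfg.H) = v;
      }
    }
  }

  // LSTM backward adds gradient into the pooled sequence as well
  std::vector<int> fwd_order(T), bwd_order(T);
  for (int t = 0; t < T; ++t) { fwd_order[t] = t; bwd_order[t] = T - 1 - t; }
  std::vector<arma::Mat<eT>> dXt(T, arma::Mat<eT>(B, cfg.tF, arma::fill::zeros));
  lstm_bwd(K.lstm[0], fwd_order, par.Wx[0], par.Wh[0], dHf,
           g.Wx[0], g.Wh[0], g.lb[0], dXt);
  lstm_bwd(K.lstm[1], bwd_order, par.Wx[1], par.Wh[1], dHb,
           g.Wx[1], g.Wh[1], g.lb[1], dXt);
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < cfg.tF; ++c) {
      eT* dcol = dPool.colptr(c);
      const eT* src = dXt[t].colptr(c);
      for (int b = 0; b < B; ++b) dcol[flT.row0(b) + t] += src[b];
    }

  // trunk stages in reverse
  arma::Mat<eT>* dcur = &K.bw_gtop;
  for (int s = S - 1; s >= 0; --s) {
    const Flat& fout = K.flp[s];
    const Flat fin_l = (s == 0) ? fl0 : K.flp[s - 1];
    // mask gap rows are zero, so this also clears any gap garbage in dcur
    *dcur %= K.drop_mask[s];
    arma::Mat<eT>& dAconv = K.bw_a[s];
    dAconv.zeros(fin_l.total, cfg.tF);
    avgpool_bwd(*dcur, fout, dAconv, fin_l, cfg.pools[s]);
    // BN backward with fused ELU derivative; zero rows of dAconv stay zero
    bn_bwd(K.bn_t[s], fin_l, par.tg[s], dAconv, g.tg[s], g.tbe[s],
           &K.trunk_a[s]);
    const arma::Mat<eT>& in = (s == 0) ? K.X1 : K.trunk_pool[s - 1];
    arma::Mat<eT>& dIn = K.bw_g[s];
    { dIn.zeros(in.n_rows, in.n_cols);
      conv_same_bwd(in, par.tW[s], dAconv, g.tW[s], g.tb[s], &dIn); }
    dcur = &dIn;
  }
  arma::Mat<eT>& dcur0 = *dcur;

  // branches: copy the relevant channel block out of dcur (block rows only,
  // so conv-spill garbage in dcur's gap rows is discarded)
  for (int br = 0; br < nb; ++br) {
    arma::Mat<eT>& dBr = K.bw_dBr;
    dBr.zeros(fl0.total, cfg.bF);
    for (int f = 0; f < cfg.bF; ++f) {
      const eT* src = dcur0.colptr(br * cfg.bF + f);
      eT* dst = dBr.colptr(f);
      for (int b = 0; b < B; ++b)
        std::copy(src + fl0.row0(b), src + fl0.row0(b) + fl0.len,
                  dst + fl0.row0(b));
    }
    arma::Mat<eT> a = cols_view(K.X1, br * cfg.bF, cfg.bF);
    bn_bwd(K.bn_b[br], fl0, par.bg[br], dBr, g.bg[br], g.bbe[br], &a);
    g.bb[br] += arma::sum(dBr, 0).t();
    const int Kk = cfg.bK[br];
    const arma::Mat<eT>& Xc = K.br_xc[br];  // im2col cached from forward
    for (int b = 0; b < B; ++b) {
      blas_gemm<eT>('T', 'N', Kk, cfg.bF, cfg.L, eT(1),
                    Xc.colptr(static_cast<arma::uword>(b) * Kk), cfg.L,
                    dBr.memptr() + fl0.row0(b), fl0.total,
                    eT(1), g.bW[br].memptr(), Kk);
    }
  }
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
List cpp_dffn_init(List cfg, int seed) {
  Cfg c = parse_cfg(cfg);
  Par<double> p = init_par<double>(c, seed);
  return par_to_list(p, c);
}

// [[Rcpp::export]]
DataFrame cpp_dffn_shapes(List par, List cfg) {
  Cfg c = parse_cfg(cfg);
  Par<float> p = par_from_list<float>(par, c);
  arma::Mat<float> X(c.L, 1, arma::fill::zeros);
  std::mt19937 gen(0);
  Cache<float> K;
  ShapeLog shapes;
  forward(c, p, X, false, gen, K, &shapes);
  CharacterVector nm(shapes.size()), dm(shapes.size());
  for (size_t i = 0; i < shapes.size(); ++i) {
    nm[i] = shapes[i].first;
    dm[i] = shapes[i].second;
  }
  return DataFrame::create(_["layer"] = nm, _["output_shape"] = dm,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_dffn_forward(List par, List cfg, arma::mat X) {
  Cfg c = parse_cfg(cfg);
  if (static_cast<int>(X.n_rows) != c.L)
    stop("input length %d != expected %d samples", static_cast<int>(X.n_rows), c.L);
  Par<float> p = par_from_list<float>(par, c);
  arma::Mat<float> Xf = arma::conv_to<arma::Mat<float>>::from(X);
  std::mt19937 gen(0);
  const int n = X.n_cols;
  arma::vec prob(n);
  arma::mat deep(n, c.fc);
  // batch in chunks to bound memory
  const int chunk = 64;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int s1 = std::min(n, s0 + chunk) - 1;
    Cache<float> K;
    arma::Mat<float> Xb = Xf.cols(s0, s1);
    forward(c, p, Xb, false, gen, K, nullptr);
    for (int i = s0; i <= s1; ++i) {
      prob[i] = K.prob[i - s0];
      deep.row(i) = arma::conv_to<arma::rowvec>::from(K.fcA.row(i - s0));
    }
  }
  return List::create(_["prob"] = prob, _["deep"] = deep);
}

// [[Rcpp::export]]
List cpp_dffn_train(List par, List cfg, arma::mat X, arma::ivec y,
                    arma::vec class_weights, arma::vec lr_per_epoch,
                    double momentum, int batch_size, int seed) {
  Cfg c = parse_cfg(cfg);
  if (static_cast<int>(X.n_rows) != c.L)
    stop("input length %d != expected %d samples", static_cast<int>(X.n_rows), c.L);
  if (X.n_cols != y.n_elem) stop("signals and labels disagree in length");
  Par<float> p = par_from_list<float>(par, c);
  Par<float> vel = zeros_like<float>(c);
  arma::Mat<float> Xf = arma::conv_to<arma::Mat<float>>::from(X);
  std::mt19937 gen(static_cast<unsigned>(seed));
  const int n = X.n_cols;
  const int epochs = lr_per_epoch.n_elem;
  arma::vec epoch_loss(epochs, arma::fill::zeros);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Cache<float> K;
  Par<float> g = zeros_like<float>(c);

  for (int e = 0; e < epochs; ++e) {
    const float lr = static_cast<float>(lr_per_epoch[e]);
    std::shuffle(idx.begin(), idx.end(), gen);
    double tot = 0.0;
    int nbatch = 0;
    for (int s0 = 0; s0 < n; s0 += batch_size) {
      const int s1 = std::min(n, s0 + batch_size);
      const int B = s1 - s0;
      arma::Mat<float> Xb(c.L, B);
      arma::ivec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.col(i) = Xf.col(idx[s0 + i]);
        yb[i] = y[idx[s0 + i]];
      }
      forward(c, p, Xb, true, gen, K, nullptr);
      arma::Col<float> dlogit;
      const double loss = wbce(K.prob, yb, class_weights, &dlogit);
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d", e + 1);
      visit_trainable(g, [](arma::Mat<float>& M) { M.zeros(); },
                      [](arma::Col<float>& v) { v.zeros(); });
      backward(c, p, Xb, K, dlogit, g);
      // SGD with momentum: v <- mom v - lr g; w <- w + v
      const float mom = static_cast<float>(momentum);
      std::vector<arma::Mat<float>*> pm, vm, gm;
      std::vector<arma::Col<float>*> pc, vc, gc;
      visit_trainable(p, [&](arma::Mat<float>& M) { pm.push_back(&M); },
                      [&](arma::Col<float>& v) { pc.push_back(&v); });
      visit_trainable(vel, [&](arma::Mat<float>& M) { vm.push_back(&M); },
                      [&](arma::Col<float>& v) { vc.push_back(&v); });
      visit_trainable(g, [&](arma::Mat<float>& M) { gm.push_back(&M); },
                      [&](arma::Col<float>& v) { gc.push_back(&v); });
      for (size_t i = 0; i < pm.size(); ++i) {
        *vm[i] = mom * (*vm[i]) - lr * (*gm[i]);
        *pm[i] += *vm[i];
      }
      for (size_t i = 0; i < pc.size(); ++i) {
        *vc[i] = mom * (*vc[i]) - lr * (*gc[i]);
        *pc[i] += *vc[i];
      }
      tot += loss;
      ++nbatch;
    }
    epoch_loss[e] = tot / std::max(1, nbatch);
  }
  return List::create(_["par"] = par_to_list(p, c), _["loss"] = epoch_loss);
}

// loss and full gradient at fixed parameters (no update); double-precision
// path intended for finite-difference verification with dropout disabled
// [[Rcpp::export]]
List cpp_dffn_loss_grad(List par, List cfg, arma::mat X, arma::ivec y,
                        arma::vec class_weights) {
  Cfg c = parse_cfg(cfg);
  Par<double> p = par_from_list<double>(par, c);
  std::mt19937 gen(0);
  Cache<double> K;
  forward(c, p, X, true, gen, K, nullptr);
  arma::Col<double> dlogit;
  const double loss = wbce(K.prob, y, class_weights, &dlogit);
  Par<double> g = zeros_like<double>(c);
  backward(c, p, X, K, dlogit, g);
  return List::create(_["loss"] = loss, _["grad"] = par_to_list(g, c));
}

// loss only (shares the exact forward semantics of the gradient path)
// [[Rcpp::export]]
double cpp_dffn_loss(List par, List cfg, arma::mat X, arma::ivec y,
                     arma::vec class_weights) {
  Cfg c = parse_cfg(cfg);
  Par<double> p = par_from_list<double>(par, c);
  std::mt19937 gen(0);
  Cache<double> K;
  forward(c, p, X, true, gen, K, nullptr);
  return wbce<double>(K.prob, y, class_weights, nullptr);
}
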