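// Batched multi-head self-attention over contiguous equal-length blocks.
//
// Sequences are stacked row-wise: row i of Q/K/V is token i, block b owns
// rows [b*Lb, (b+1)*Lb).  Head h owns columns [h*dh, (h+1)*dh) with
// dh = d/n_heads.  key_mask is 0/1 per row; masked rows are excluded as
// attention *keys* (their own query rows still produce output, which
// callers discard).  drop_mask, when given, is an inverted-dropout
// multiplier applied to the softmax probabilities; it is laid out like the
// returned probability matrix: (Lb*n_heads) x N, where column r0+q holds
// the attention distribution of query q of its block, heads stacked
// (head h in rows [h*Lb, (h+1)*Lb)).
//
// Head slices are repacked per block into (Lb x dh) buffers whose key axis
// is unit-stride, so every contraction is a run of contiguous length-Lb
// axpy/dot loops the compiler auto-vectorizes; block sizes are tens of
// tokens, far below profitable BLAS dispatch.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

// fast exp for the softmax: 2^z split into integer/fraction, degree-8
// Taylor on the fractional part (relative error ~1e-10); arguments <= 0
static inline double fast_exp(double x) {
  if (x < -700.0) return 0.0;
  const double y = x * 1.4426950408889634;  // x / ln 2
  int64_t i = (int64_t) y;
  if (y < (double) i) --i;                  // floor toward -inf
  const double t = (y - (double) i) * 0.6931471805599453;
  const double p = 1.0 + t * (1.0 + t * (0.5 + t * (1.0 / 6 +
      t * (1.0 / 24 + t * (1.0 / 120 + t * (1.0 / 720 +
      t * (1.0 / 5040 + t * (1.0 / 40320))))))));
  const int64_t bits = (i + 1023) << 52;    // 2^i as a double
  double s2;
  std::memcpy(&s2, &bits, sizeof(s2));
  return p * s2;
}

// pack head columns of a block: out[j*Lb + i] = X[r0+i, c0+j]
// (contiguous per source column; token axis unit-stride in the buffer)
static inline void load_blockT(const double* X, int N, int r0, int c0,
                               int Lb, int dh, double* out) {
  for (int j = 0; j < dh; ++j) {
    const double* col = X + (size_t)(c0 + j) * N + r0;
    double* dst = out + (size_t) j * Lb;
    for (int i = 0; i < Lb; ++i) dst[i] = col[i];
  }
}

static inline void store_blockT(double* X, int N, int r0, int c0,
                                int Lb, int dh, const double* in) {
  for (int j = 0; j < dh; ++j) {
    double* col = X + (size_t)(c0 + j) * N + r0;
    const double* src = in + (size_t) j * Lb;
    for (int i = 0; i < Lb; ++i) col[i] = src[i];
  }
}

// [[Rcpp::export]]
List mha_forward_cpp(const NumericMatrix& Q, const NumericMatrix& K,
                     const NumericMatrix& V, int block_len, int n_heads,
                     const NumericVector& key_mask,
                     Nullable<NumericMatrix> drop_mask = R_NilValue) {
  const int N = Q.nrow(), d = Q.ncol();
  const int Lb = block_len, nb = N / Lb, dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  const int Lbh = Lb * n_heads;

  NumericMatrix ctx(N, d);
  const bool has_drop = drop_mask.isNotNull();
  NumericMatrix M;
  if (has_drop) M = drop_mask.get();

  std::vector<double> QT(Lb * dh), KT(Lb * dh), VT(Lb * dh), CT(Lb * dh),
      P(Lb);

  for (int b = 0; b < nb; ++b) {
    const int r0 = b * Lb;
    int n_masked = 0;
    for (int j = 0; j < Lb; ++j)
      if (key_mask[r0 + j] < 0.5) ++n_masked;
    if (n_masked == Lb) continue;  // all padding: zero context
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      load_blockT(&Q[0], N, r0, c0, Lb, dh, QT.data());
      load_blockT(&K[0], N, r0, c0, Lb, dh, KT.data());
      load_blockT(&V[0], N, r0, c0, Lb, dh, VT.data());
      for (int q = 0; q < Lb; ++q) {
        // scores for query q over all keys: outer-product accumulation
        double* s = P.data();
        {
          const double c = QT[q] * scale;
          const double* Kj = KT.data();
          for (int k = 0; k < Lb; ++k) s[k] = c * Kj[k];
        }
        for (int j = 1; j < dh; ++j) {
          const double c = QT[(size_t) j * Lb + q] * scale;
          const double* Kj = KT.data() + (size_t) j * Lb;
          for (int k = 0; k < Lb; ++k) s[k] += c * Kj[k];
        }
        if (n_masked)
          for (int k = 0; k < Lb; ++k)
            if (key_mask[r0 + k] < 0.5) s[k] = -1e300;
        double mx = -1e300;
        for (int k = 0; k < Lb; ++k) if (s[k] > mx) mx = s[k];
        double Z = 0;
        for (int k = 0; k < Lb; ++k) {
          const double e = (s[k] <= -1e299) ? 0.0 : fast_exp(s[k] - mx);
          s[k] = e;
          Z += e;
        }
        const double iZ = 1.0 / Z;
        for (int k = 0; k < Lb; ++k) s[k] *= iZ;
        if (has_drop) {
          const double* mcol = &M[0] + (size_t)(r0 + q) * Lbh + h * Lb;
          for (int k = 0; k < Lb; ++k) s[k] *= mcol[k];
        }
        // context: ctx(q, j) = dot(P, V(:, j))
        for (int j = 0; j < dh; ++j) {
          const double* Vj = VT.data() + (size_t) j * Lb;
          double acc = 0;
          for (int k = 0; k < Lb; ++k) acc += s[k] * Vj[k];
          CT[(size_t) j * Lb + q] = acc;
        }
      }
      store_blockT(&ctx[0], N, r0, c0, Lb, dh, CT.data());
    }
  }
  return List::create(_["ctx"] = ctx);
}

// [[Rcpp::export]]
List mha_backward_cpp(const NumericMatrix& dCtx, const NumericMatrix& Q,
                      const NumericMatrix& K, const NumericMatrix& V,
                      int block_len, int n_heads,
                      const NumericVector& key_mask,
                      Nullable<NumericMatrix> drop_mask = R_NilValue) {
  const int N = Q.nrow(), d = Q.ncol();
  const int Lb = block_len, nb = N / Lb, dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  const int Lbh = Lb * n_heads;

  NumericMatrix dQ(N, d), dK(N, d), dV(N, d);
  const bool has_drop = drop_mask.isNotNull();
  NumericMatrix M;
  if (has_drop) M = drop_mask.get();

  std::vector<double> QT(Lb * dh), KT(Lb * dh), VT(Lb * dh), dCT(Lb * dh),
      dQT(Lb * dh), dKT(Lb * dh), dVT(Lb * dh),
      P0(Lb), Pd(Lb), dP(Lb);

  for (int b = 0; b < nb; ++b) {
    const int r0 = b * Lb;
    int n_masked = 0;
    for (int j = 0; j < Lb; ++j)
      if (key_mask[r0 + j] < 0.5) ++n_masked;
    if (n_masked == Lb) continue;
    for (int h = 0; h < n_heads; ++h) {
      const int c0 = h * dh;
      load_blockT(&Q[0], N, r0, c0, Lb, dh, QT.data());
      load_blockT(&K[0], N, r0, c0, Lb, dh, KT.data());
      load_blockT(&V[0], N, r0, c0, Lb, dh, VT.data());
      load_blockT(&dCtx[0], N, r0, c0, Lb, dh, dCT.data());
      std::fill(dKT.begin(), dKT.end(), 0.0);
      std::fill(dVT.begin(), dVT.end(), 0.0);
      for (int q = 0; q < Lb; ++q) {
        const double* mcol = has_drop
            ? &M[0] + (size_t)(r0 + q) * Lbh + h * Lb : nullptr;
        // recompute the softmax row for this query
        {
          double* s = P0.data();
          const double c0q = QT[q] * scale;
          const double* Kj = KT.data();
          for (int k = 0; k < Lb; ++k) s[k] = c0q * Kj[k];
          for (int j = 1; j < dh; ++j) {
            const double c = QT[(size_t) j * Lb + q] * scale;
            const double* Kjj = KT.data() + (size_t) j * Lb;
            for (int k = 0; k < Lb; ++k) s[k] += c * Kjj[k];
          }
          if (n_masked)
            for (int k = 0; k < Lb; ++k)
              if (key_mask[r0 + k] < 0.5) s[k] = -1e300;
          double mx = -1e300;
          for (int k = 0; k < Lb; ++k) if (s[k] > mx) mx = s[k];
          double Z = 0;
          for (int k = 0; k < Lb; ++k) {
            const double e = (s[k] <= -1e299) ? 0.0 : fast_exp(s[k] - mx);
            s[k] = e;
            Z += e;
          }
          const double iZ = 1.0 / Z;
          for (int k = 0; k < Lb; ++k) s[k] *= iZ;
        }
        for (int k = 0; k < Lb; ++k)
          Pd[k] = has_drop ? P0[k] * mcol[k] : P0[k];
        // dV(:,k) += Pd[k] * dC(q,:);  dP[k] = dot(dC(q,:), V(:,k))
        for (int k = 0; k < Lb; ++k) dP[k] = 0;
        for (int j = 0; j < dh; ++j) {
          const double c = dCT[(size_t) j * Lb + q];
          if (c == 0) continue;
          const double* Vj = VT.data() + (size_t) j * Lb;
          double* dVj = dVT.data() + (size_t) j * Lb;
          for (int k = 0; k < Lb; ++k) {
            dVj[k] += Pd[k] * c;
            dP[k] += c * Vj[k];
          }
        }
        if (has_drop)
          for (int k = 0; k < Lb; ++k) dP[k] *= mcol[k];
        // softmax backward: dS = P0 .* (dP - sum(dP .* P0)), then scale
        double rs = 0;
        for (int k = 0; k < Lb; ++k) rs += dP[k] * P0[k];
        for (int k = 0; k < Lb; ++k)
          dP[k] = P0[k] * (dP[k] - rs) * scale;  // now dS
        // dQ(q,j) = dot(dS, K(:,j));  dK(:,j) += Q(q,j) * dS
        for (int j = 0; j < dh; ++j) {
          const double* Kj = KT.data() + (size_t) j * Lb;
          double* dKj = dKT.data() + (size_t) j * Lb;
          const double qv = QT[(size_t) j * Lb + q];
          double acc = 0;
          for (int k = 0; k < Lb; ++k) {
            acc += dP[k] * Kj[k];
            dKj[k] += qv * dP[k];
          }
          dQT[(size_t) j * Lb + q] = acc;
        }
      }
      store_blockT(&dQ[0], N, r0, c0, Lb, dh, dQT.data());
      store_blockT(&dK[0], N, r0, c0, Lb, dh, dKT.data());
      store_blockT(&dV[0], N, r0, c0, Lb, dh, dVT.data());
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
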