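// Batched tensor contractions for the multi-head attention layers.
// Arrays follow R's column-major layout:
//   X (B, L, d): X[b + B*(l + L*dd)]
//   P (B, Lq, Lk, H): P[b + B*(i + Lq*(j + Lk*h))]
// Heads partition the feature axis: feature dd belongs to head dd / dk.

#include <Rcpp.h>
using namespace Rcpp;

// S[b,i,j,h] = scale * sum_{dd in head h} Q[b,i,dd] * K[b,j,dd]
// [[Rcpp::export(name = ".bat_scores")]]
NumericVector bat_scores(NumericVector Q, NumericVector K, int n_heads,
                         double scale) {
  IntegerVector dq = Q.attr("dim"), dk_ = K.attr("dim");
  const int B = dq[0], Lq = dq[1], d = dq[2], Lk = dk_[1];
  const int dk = d / n_heads;
  NumericVector S(static_cast<R_xlen_t>(B) * Lq * Lk * n_heads);
  S.attr("dim") = IntegerVector::create(B, Lq, Lk, n_heads);
  const double* q = Q.begin();
  const double* k = K.begin();
  double* s = S.begin();
  for (int h = 0; h < n_heads; ++h) {
    for (int j = 0; j < Lk; ++j) {
      for (int i = 0; i < Lq; ++i) {
        double* srow = s + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h));
        for (int dd = h * dk; dd < (h + 1) * dk; ++dd) {
          const double* qrow = q + (R_xlen_t)B * (i + (R_xlen_t)Lq * dd);
          const double* krow = k + (R_xlen_t)B * (j + (R_xlen_t)Lk * dd);
          for (int b = 0; b < B; ++b) srow[b] += qrow[b] * krow[b];
        }
        for (int b = 0; b < B; ++b) srow[b] *= scale;
      }
    }
  }
  return S;
}

// O[b,i,dd] = sum_j P[b,i,j,h(dd)] * V[b,j,dd]
// [[Rcpp::export(name = ".bat_attend")]]
NumericVector bat_attend(NumericVector P, NumericVector V) {
  IntegerVector dp = P.attr("dim"), dv = V.attr("dim");
  const int B = dp[0], Lq = dp[1], Lk = dp[2], H = dp[3], d = dv[2];
  const int dk = d / H;
  NumericVector O(static_cast<R_xlen_t>(B) * Lq * d);
  O.attr("dim") = IntegerVector::create(B, Lq, d);
  const double* p = P.begin();
  const double* v = V.begin();
  double* o = O.begin();
  for (int dd = 0; dd < d; ++dd) {
    const int h = dd / dk;
    for (int i = 0; i < Lq; ++i) {
      double* orow = o + (R_xlen_t)B * (i + (R_xlen_t)Lq * dd);
      for (int j = 0; j < Lk; ++j) {
        const double* prow = p + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h));
        const double* vrow = v + (R_xlen_t)B * (j + (R_xlen_t)Lk * dd);
        for (int b = 0; b < B; ++b) orow[b] += prow[b] * vrow[b];
      }
    }
  }
  return O;
}

// Y[b,j,dd] = sum_i P[b,i,j,h(dd)] * X[b,i,dd]   (transposed contraction)
// [[Rcpp::export(name = ".bat_attend_t")]]
NumericVector bat_attend_t(NumericVector P, NumericVector X) {
  IntegerVector dp = P.attr("dim"), dx = X.attr("dim");
  const int B = dp[0], Lq = dp[1], Lk = dp[2], H = dp[3], d = dx[2];
  const int dk = d / H;
  NumericVector Y(static_cast<R_xlen_t>(B) * Lk * d);
  Y.attr("dim") = IntegerVector::create(B, Lk, d);
  const double* p = P.begin();
  const double* x = X.begin();
  double* y = Y.begin();
  for (int dd = 0; dd < d; ++dd) {
    const int h = dd / dk;
    for (int j = 0; j < Lk; ++j) {
      double* yrow = y + (R_xlen_t)B * (j + (R_xlen_t)Lk * dd);
      for (int i = 0; i < Lq; ++i) {
        const double* prow = p + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h));
        const double* xrow = x + (R_xlen_t)B * (i + (R_xlen_t)Lq * dd);
        for (int b = 0; b < B; ++b) yrow[b] += prow[b] * xrow[b];
      }
    }
  }
  return Y;
}

// Row-normalize scores over the key axis with pad-key masking.
// mask: B x Lk, 0 marks pad keys (excluded from the normalization).
// Fully masked (query, head) rows yield all-zero probabilities.
// [[Rcpp::export(name = ".masked_softmax")]]
NumericVector masked_softmax(NumericVector S, NumericMatrix mask) {
  IntegerVector ds = S.attr("dim");
  const int B = ds[0], Lq = ds[1], Lk = ds[2], H = ds[3];
  NumericVector P(clone(S));
  P.attr("dim") = ds;
  double* p = P.begin();
  for (int h = 0; h < H; ++h) {
    for (int i = 0; i < Lq; ++i) {
      for (int b = 0; b < B; ++b) {
        double mx = R_NegInf;
        for (int j = 0; j < Lk; ++j) {
          if (mask(b, j) != 0) {
            const double v = p[b + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h))];
            if (v > mx) mx = v;
          }
        }
        double z = 0.0;
        for (int j = 0; j < Lk; ++j) {
          const R_xlen_t at = b + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h));
          if (mask(b, j) != 0 && R_finite(mx)) {
            p[at] = std::exp(p[at] - mx);
            z += p[at];
          } else {
            p[at] = 0.0;
          }
        }
        if (z > 0.0) {
          for (int j = 0; j < Lk; ++j) {
            const R_xlen_t at = b + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h));
            p[at] /= z;
          }
        }
      }
    }
  }
  return P;
}

// dS = P * (dP - sum_j dP[.,j] * P[.,j])  (softmax Jacobian application)
// [[Rcpp::export(name = ".softmax_backward")]]
NumericVector softmax_backward(NumericVector P, NumericVector dP) {
  IntegerVector dp = P.attr("dim");
  const int B = dp[0], Lq = dp[1], Lk = dp[2], H = dp[3];
  NumericVector dS(static_cast<R_xlen_t>(B) * Lq * Lk * H);
  dS.attr("dim") = dp;
  const double* p = P.begin();
  const double* g = dP.begin();
  double* out = dS.begin();
  for (int h = 0; h < H; ++h) {
    for (int i = 0; i < Lq; ++i) {
      for (int b = 0; b < B; ++b) {
        double c = 0.0;
        for (int j = 0; j < Lk; ++j) {
          const R_xlen_t at = b + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h));
          c += g[at] * p[at];
        }
        for (int j = 0; j < Lk; ++j) {
          const R_xlen_t at = b + (R_xlen_t)B * (i + (R_xlen_t)Lq * (j + (R_xlen_t)Lk * h));
          out[at] = p[at] * (g[at] - c);
        }
      }
    }
  }
  return dS;
}
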