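#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// External product accumulation over the discretized torus (mod 2^32).
//
// digits: ((k+1)*l) x N integer matrix of gadget-decomposition digits,
//         each in (-Bg/2, Bg/2].
// rows:   ((k+1)*l) x ((k+1)*N) numeric matrix; row r holds the TGSW row's
//         TLWE sample flattened as (a_1 | ... | a_k | b), coefficients in
//         [0, 2^32).
// Returns the flattened (k+1)*N output sample: sum_r digits_r (*) rows_r,
// with (*) the negacyclic polynomial product in Z[X]/(X^N + 1).
//
// Exactness: |digit| <= Bg/2 <= 2^15 and coefficients < 2^32 so each term
// fits int64; accumulation wraps in uint64 and 2^32 divides 2^64, so the
// final mask gives the exact mod-2^32 result.
// [[Rcpp::export]]
NumericVector ext_prod_cpp(IntegerMatrix digits, NumericMatrix rows,
                           int k, int N) {
  const int nr = digits.nrow();
  const int len = (k + 1) * N;
  std::vector<uint64_t> acc(len, 0);
  for (int r = 0; r < nr; ++r) {
    for (int i = 0; i < N; ++i) {
      const int64_t d = digits(r, i);
      if (d == 0) continue;
      for (int comp = 0; comp <= k; ++comp) {
        const int base = comp * N;
        for (int j = 0; j < N; ++j) {
          int idx = i + j;
          int64_t term = d * (int64_t) rows(r, base + j);
          if (idx >= N) { idx -= N; term = -term; }
          acc[base + idx] += (uint64_t) term;
        }
      }
    }
  }
  NumericVector out(len);
  for (int m = 0; m < len; ++m)
    out[m] = (double) (acc[m] & 0xFFFFFFFFULL);
  return out;
}
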