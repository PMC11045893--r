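#include <Rcpp.h>
#include <cstdint>

// Counter-based Squares generator (Widynski), 32-bit output variant:
// four middle-square rounds over a 64-bit counter*key seed.
static inline uint32_t squares32_one(uint64_t ctr, uint64_t key) {
  uint64_t x, y, z;
  y = x = ctr * key;
  z = y + key;
  x = x * x + y; x = (x >> 32) | (x << 32);   // round 1
  x = x * x + z; x = (x >> 32) | (x << 32);   // round 2
  x = x * x + y; x = (x >> 32) | (x << 32);   // round 3
  return (uint64_t)(x * x + z) >> 32;         // round 4
}

// Counters and keys are passed as doubles (exact for values < 2^53, far
// beyond any counter this library addresses) and truncated to uint64.
// [[Rcpp::export(name = ".squares32_cpp")]]
Rcpp::NumericVector squares32_cpp(Rcpp::NumericVector counter,
                                  Rcpp::NumericVector key) {
  R_xlen_t n = counter.size();
  R_xlen_t nk = key.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t c = (uint64_t)counter[i];
    uint64_t k = (uint64_t)key[nk == 1 ? 0 : i];
    out[i] = (double)squares32_one(c, k);
  }
  return out;
}

// [[Rcpp::export(name = ".squares_u01_cpp")]]
Rcpp::NumericVector squares_u01_cpp(Rcpp::NumericVector counter,
                                    Rcpp::NumericVector key) {
  R_xlen_t n = counter.size();
  R_xlen_t nk = key.size();
  Rcpp::NumericVector out(n);
  const double scale = 1.0 / 4294967296.0;    // 2^-32
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t c = (uint64_t)counter[i];
    uint64_t k = (uint64_t)key[nk == 1 ? 0 : i];
    out[i] = (double)squares32_one(c, k) * scale;
  }
  return out;
}
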