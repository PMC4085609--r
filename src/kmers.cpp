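#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else (N, ...) is invalid.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Canonical key of the k-mer starting at position i: min(forward, reverse
// complement) of the 2-bit packed value. Keys fit exactly in a double for
// k <= 26 (2k <= 52 bits), which the R wrappers enforce.
// Returns -1 if the window contains an invalid base.
static inline int64_t canonical_at(const char* s, int i, int k) {
  int64_t fwd = 0, rev = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(s[i + j]);
    if (c < 0) return -1;
    fwd = (fwd << 2) | c;
    rev |= ((int64_t)(3 - c)) << (2 * j);
  }
  return fwd < rev ? fwd : rev;
}

// [[Rcpp::export]]
List cpp_kmer_index(CharacterVector seqs, int k) {
  std::unordered_map<int64_t, int> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    int n = LENGTH(STRING_ELT(seqs, s));
    for (int i = 0; i + k <= n; ++i) {
      int64_t key = canonical_at(str, i, k);
      if (key >= 0) ++counts[key];
    }
  }
  NumericVector keys(counts.size());
  IntegerVector cnt(counts.size());
  R_xlen_t i = 0;
  for (const auto& kv : counts) {
    keys[i] = (double)kv.first;
    cnt[i] = kv.second;
    ++i;
  }
  return List::create(_["key"] = keys, _["count"] = cnt);
}

// Per-position repeat coverage: position p is covered if it lies within the
// k-span of any k-mer whose index count is >= threshold.
// [[Rcpp::export]]
List cpp_kmer_coverage(CharacterVector seqs, int k, NumericVector keys,
                       IntegerVector counts, int threshold) {
  std::unordered_map<int64_t, int> idx;
  idx.reserve(keys.size() * 2);
  for (R_xlen_t i = 0; i < keys.size(); ++i)
    idx[(int64_t)keys[i]] = counts[i];
  List out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    int n = LENGTH(STRING_ELT(seqs, s));
    LogicalVector cov(n, false);
    int covered_until = -1;  // rightmost covered position so far (exclusive)
    for (int i = 0; i + k <= n; ++i) {
      int64_t key = canonical_at(str, i, k);
      if (key < 0) continue;
      auto it = idx.find(key);
      if (it != idx.end() && it->second >= threshold) {
        int from = i > covered_until ? i : covered_until;
        for (int p = from; p < i + k; ++p) cov[p] = true;
        covered_until = i + k;
      }
    }
    out[s] = cov;
  }
  return out;
}
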