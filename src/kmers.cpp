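#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit DNA packing; k <= 32. Windows containing any non-ACGT base are
// skipped, matching the behaviour of standard k-mer counters on N runs.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char alpha[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = alpha[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
DataFrame kmer_count_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::unordered_map<uint64_t, double> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, s));
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int c = base_code(str[i]);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        counts[canon] += 1.0;
      }
    }
  }
  R_xlen_t m = counts.size();
  CharacterVector kmer(m);
  NumericVector count(m);
  R_xlen_t i = 0;
  for (auto &kv : counts) {
    kmer[i] = decode_kmer(kv.first, k);
    count[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                           _["stringsAsFactors"] = false);
}

// Positions i (0-based) where the k-mer starting at i equals, exactly, the
// k-mer starting at i + k (both windows free of non-ACGT characters).
// [[Rcpp::export]]
IntegerVector tandem_positions_cpp(std::string seq, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  R_xlen_t n = (R_xlen_t)seq.size();
  std::vector<int> out;
  if (n < 2 * k) return IntegerVector(0);
  // rolling codes with validity tracking
  std::vector<uint64_t> code(n - k + 1, 0);
  std::vector<char> ok(n - k + 1, 0);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0;
  int valid = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      code[i - k + 1] = fwd;
      ok[i - k + 1] = 1;
    }
  }
  for (R_xlen_t i = 0; i + k < (R_xlen_t)code.size(); ++i) {
    if (ok[i] && ok[i + k] && code[i] == code[i + k]) out.push_back((int)i);
  }
  return wrap(out);
}
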