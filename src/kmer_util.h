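#ifndef SKIMGENE_KMER_UTIL_H
#define SKIMGENE_KMER_UTIL_H

#include <cstdint>
#include <string>

// 2-bit packed k-mers, A=0 C=1 G=2 T=3, leftmost base most significant.
// k <= 31 so a code always fits a 64-bit word with the top bits clear.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t kmer_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
}

// reverse complement of a 2-bit packed k-mer
static inline uint64_t revcomp_code(uint64_t v, int k) {
  v = ~v;
  v = ((v >> 2) & 0x3333333333333333ULL) | ((v & 0x3333333333333333ULL) << 2);
  v = ((v >> 4) & 0x0F0F0F0F0F0F0F0FULL) | ((v & 0x0F0F0F0F0F0F0F0FULL) << 4);
  v = ((v >> 8) & 0x00FF00FF00FF00FFULL) | ((v & 0x00FF00FF00FF00FFULL) << 8);
  v = ((v >> 16) & 0x0000FFFF0000FFFFULL) | ((v & 0x0000FFFF0000FFFFULL) << 16);
  v = (v >> 32) | (v << 32);
  return v >> (64 - 2 * k);
}

static inline uint64_t canonical_code(uint64_t v, int k) {
  uint64_t r = revcomp_code(v, k);
  return (r < v) ? r : v;
}

static inline std::string decode_code(uint64_t v, int k) {
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = CODE_BASE[v & 3ULL];
    v >>= 2;
  }
  return s;
}

// Encode a full string; returns false if any non-ACGT base present.
static inline bool encode_string(const std::string& s, int k, uint64_t* out) {
  if ((int)s.size() != k) return false;
  uint64_t v = 0;
  for (char c : s) {
    int b = base_code(c);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  *out = v;
  return true;
}

// Visit every valid k-mer window of seq; windows containing ambiguous
// bases are skipped. f(pos, code) with pos the 0-based window start.
template <typename F>
static inline void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = kmer_mask(k);
  uint64_t cur = 0;
  int run = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(i - k + 1, cur);
  }
}

#endif
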