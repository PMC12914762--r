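// Affine-gap local alignment (Gotoh) used for reference-based trimming.
// A gap of length L costs open + L * extend, matching the common
// convention of alignment libraries.

#include <Rcpp.h>
#include <string>
#include <vector>
#include "kmer_util.h"

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_local_align(std::string pattern, std::string subject,
                     double match = 1, double mismatch = -2,
                     double gap_open = 5, double gap_extend = 2) {
  const int m = (int)pattern.size();
  const int n = (int)subject.size();
  const double NEG = -1e18;
  const size_t W = (size_t)n + 1;
  // H: best local score at (i,j); E: gap in subject (vertical move);
  // F: gap in pattern (horizontal move).
  std::vector<double> Hprev(W, 0.0), Hcur(W, 0.0);
  std::vector<double> Eprev(W, NEG), Ecur(W, NEG);
  std::vector<double> Fcur(W, NEG);
  // per-cell traceback, 4 bits: bits 0-1 H-state (0 stop, 1 diag, 2 from
  // E, 3 from F); bit 2: E opened here; bit 3: F opened here.
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 0);
  double best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    Ecur[0] = NEG;
    Fcur[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      unsigned char t = 0;
      double e_open = Hprev[j] - gap_open - gap_extend;
      double e_ext = Eprev[j] - gap_extend;
      double e = e_open;
      if (e_ext > e_open) { e = e_ext; t |= 4; }
      double f_open = Hcur[j - 1] - gap_open - gap_extend;
      double f_ext = Fcur[j - 1] - gap_extend;
      double f = f_open;
      if (f_ext > f_open) { f = f_ext; t |= 8; }
      double sub = (pattern[(size_t)(i - 1)] == subject[(size_t)(j - 1)])
                       ? match : mismatch;
      double d = Hprev[j - 1] + sub;
      double h = d;
      unsigned char hs = 1;
      if (e > h) { h = e; hs = 2; }
      if (f > h) { h = f; hs = 3; }
      if (h <= 0) { h = 0; hs = 0; }
      Hcur[j] = h;
      Ecur[j] = e;
      Fcur[j] = f;
      tb[(size_t)i * W + j] = (unsigned char)(t | hs);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  int matches = 0, mismatches = 0, gap_bases = 0;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * W + j];
    if (state == 0) {
      unsigned char hs = t & 3;
      if (hs == 0) break;
      if (hs == 1) {
        if (pattern[(size_t)(i - 1)] == subject[(size_t)(j - 1)]) matches++;
        else mismatches++;
        i--; j--;
      } else if (hs == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // E: vertical gap step
      gap_bases++;
      bool extended = (t & 4) != 0;
      i--;
      if (!extended) state = 0;
    } else {  // F: horizontal gap step
      gap_bases++;
      bool extended = (t & 8) != 0;
      j--;
      if (!extended) state = 0;
    }
  }
  double cols = matches + mismatches + gap_bases;
  return List::create(
      _["score"] = best,
      _["p_start"] = i,    // 0-based inclusive start on pattern
      _["p_end"] = bi,     // exclusive end
      _["s_start"] = j,
      _["s_end"] = bj,
      _["matches"] = matches,
      _["mismatches"] = mismatches,
      _["gap_bases"] = gap_bases,
      _["identity"] = cols > 0 ? matches / cols : 0.0);
}
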