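// Read-screening kernels: per-gene reference k-mer sets, direction-call
// sequences (forward/reverse k-mer match orientation with run statistics),
// and strand-insensitive hit counts used by baiting re-filters.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include "kmer_util.h"

using namespace Rcpp;

typedef std::unordered_set<uint64_t> KmerSet;

// Forward-strand k-mer set of one or more reference sequences.
// [[Rcpp::export]]
SEXP cpp_kmer_set(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  XPtr<KmerSet> p(new KmerSet(), true);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_each_kmer(s, k, [&](int, uint64_t code) { p->insert(code); });
  }
  p.attr("k") = k;
  return p;
}

// [[Rcpp::export]]
double cpp_kmer_set_size(SEXP xp) {
  XPtr<KmerSet> p(xp);
  return (double)p->size();
}

// Direction-call statistics per read. A window calls F when the forward
// k-mer is in the reference set and its reverse complement is not, R in
// the converse case; windows matching both ways or neither are ignored.
// p1/p2 are the fractions of k-mer windows matching the reference in the
// forward (resp. reverse) orientation inside the span of same-direction
// calls (whole-region convention).
// [[Rcpp::export]]
DataFrame cpp_direction_stats(CharacterVector reads, SEXP set_xp, int k,
                              bool keep_calls) {
  XPtr<KmerSet> ref(set_xp);
  const R_xlen_t n = reads.size();
  IntegerVector n1(n), n2(n), runs(n), longest_f(n), longest_r(n);
  NumericVector p1(n), p2(n);
  CharacterVector calls_out(keep_calls ? n : 0);

  std::vector<int> call;      // 1 = F, 2 = R, per informative window (compressed)
  std::vector<int> win_call;  // per valid window: 0/1/2
  std::vector<char> win_f;    // forward k-mer matches reference
  std::vector<char> win_r;    // reverse complement matches reference

  for (R_xlen_t i = 0; i < n; ++i) {
    call.clear(); win_call.clear(); win_f.clear(); win_r.clear();
    std::string s = as<std::string>(reads[i]);
    for_each_kmer(s, k, [&](int, uint64_t code) {
      bool f = ref->count(code) > 0;
      bool r = ref->count(revcomp_code(code, k)) > 0;
      win_f.push_back(f ? 1 : 0);
      win_r.push_back(r ? 1 : 0);
      int c = (f && !r) ? 1 : ((r && !f) ? 2 : 0);
      win_call.push_back(c);
      if (c) call.push_back(c);
    });
    int cn1 = 0, cn2 = 0, r_runs = 0, lf = 0, lr = 0, cur_len = 0, cur = 0;
    for (int c : call) {
      if (c == 1) cn1++; else cn2++;
      if (c != cur) { r_runs++; cur = c; cur_len = 1; } else cur_len++;
      if (c == 1 && cur_len > lf) lf = cur_len;
      if (c == 2 && cur_len > lr) lr = cur_len;
    }
    n1[i] = cn1; n2[i] = cn2; runs[i] = r_runs;
    longest_f[i] = lf; longest_r[i] = lr;
    // region identity proportions
    double pp1 = NA_REAL, pp2 = NA_REAL;
    int firstF = -1, lastF = -1, firstR = -1, lastR = -1;
    for (size_t w = 0; w < win_call.size(); ++w) {
      if (win_call[w] == 1) { if (firstF < 0) firstF = (int)w; lastF = (int)w; }
      if (win_call[w] == 2) { if (firstR < 0) firstR = (int)w; lastR = (int)w; }
    }
    if (firstF >= 0) {
      int tot = lastF - firstF + 1, hit = 0;
      for (int w = firstF; w <= lastF; ++w) hit += win_f[(size_t)w];
      pp1 = (double)hit / (double)tot;
    }
    if (firstR >= 0) {
      int tot = lastR - firstR + 1, hit = 0;
      for (int w = firstR; w <= lastR; ++w) hit += win_r[(size_t)w];
      pp2 = (double)hit / (double)tot;
    }
    p1[i] = pp1; p2[i] = pp2;
    if (keep_calls) {
      std::string cs;
      cs.reserve(call.size());
      for (int c : call) cs.push_back(c == 1 ? 'F' : 'R');
      calls_out[i] = cs;
    }
  }
  List cols = List::create(
      _["n1"] = n1, _["n2"] = n2, _["r"] = runs,
      _["longest_f"] = longest_f, _["longest_r"] = longest_r,
      _["p1"] = p1, _["p2"] = p2);
  if (keep_calls) cols.push_back(calls_out, "calls");
  DataFrame out(cols);
  return out;
}

// Number of k-mer windows of each read present in the reference set on
// either strand.
// [[Rcpp::export]]
IntegerVector cpp_hit_counts(CharacterVector reads, SEXP set_xp, int k) {
  XPtr<KmerSet> ref(set_xp);
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    int hits = 0;
    for_each_kmer(s, k, [&](int, uint64_t code) {
      if (ref->count(code) || ref->count(revcomp_code(code, k))) hits++;
    });
    out[i] = hits;
  }
  return out;
}
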