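// Weighted de Bruijn assembly: anchor k-mer scoring for adaptive k
// selection, canonical-k-mer graph construction, and the reference-guided
// greedy walk with total tie-breaking and soft-boundary trimming.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include "kmer_util.h"

using namespace Rcpp;

// Count of unique anchor k-mers per read. An anchor is a k-mer occurring
// exactly once in the read (canonical sense) and present in the reference;
// each consecutive run of anchors contributes ceil(run_length / run_cap)
// unique anchors.
// [[Rcpp::export]]
IntegerVector cpp_anchor_n(CharacterVector reads, CharacterVector ref, int k,
                           int run_cap) {
  std::unordered_set<uint64_t> refset;
  for (R_xlen_t i = 0; i < ref.size(); ++i) {
    std::string s = as<std::string>(ref[i]);
    for_each_kmer(s, k, [&](int, uint64_t code) {
      refset.insert(canonical_code(code, k));
    });
  }
  IntegerVector out(reads.size());
  std::unordered_map<uint64_t, int> occ;
  std::vector<uint64_t> codes;
  std::vector<int> pos;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    occ.clear(); codes.clear(); pos.clear();
    std::string s = as<std::string>(reads[i]);
    for_each_kmer(s, k, [&](int p, uint64_t code) {
      uint64_t c = canonical_code(code, k);
      occ[c]++;
      codes.push_back(c);
      pos.push_back(p);
    });
    int N = 0, run = 0, last_pos = -2;
    for (size_t j = 0; j < codes.size(); ++j) {
      bool anchor = occ[codes[j]] == 1 && refset.count(codes[j]) > 0;
      bool contiguous = (pos[j] == last_pos + 1);
      if (anchor) {
        run = (run > 0 && contiguous) ? run + 1 : 1;
        if (run == 1 || (run_cap > 0 && (run - 1) % run_cap == 0)) N++;
        last_pos = pos[j];
      } else {
        run = 0;
        last_pos = pos[j];
        continue;
      }
    }
    out[i] = N;
  }
  return out;
}

struct DBG {
  int k;
  std::unordered_map<uint64_t, int> w;  // canonical code -> read multiplicity
  std::unordered_set<uint64_t> ref_canon;
  std::unordered_set<uint64_t> ref_fwd;  // reference-strand codes, for orientation
};

static void build_dbg(DBG& g, CharacterVector reads, CharacterVector ref, int k) {
  g.k = k;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = Rcpp::as<std::string>(reads[i]);
    for_each_kmer(s, k, [&](int, uint64_t code) {
      g.w[canonical_code(code, k)]++;
    });
  }
  for (R_xlen_t i = 0; i < ref.size(); ++i) {
    std::string s = Rcpp::as<std::string>(ref[i]);
    for_each_kmer(s, k, [&](int, uint64_t code) {
      g.ref_fwd.insert(code);
      g.ref_canon.insert(canonical_code(code, k));
    });
  }
}

// Graph nodes for inspection/testing.
// [[Rcpp::export]]
DataFrame cpp_graph_nodes(CharacterVector reads, CharacterVector ref, int k) {
  DBG g;
  build_dbg(g, reads, ref, k);
  std::vector<std::pair<uint64_t, int> > nodes(g.w.begin(), g.w.end());
  std::sort(nodes.begin(), nodes.end());
  CharacterVector kmer(nodes.size());
  IntegerVector weight(nodes.size());
  LogicalVector mark(nodes.size());
  for (size_t i = 0; i < nodes.size(); ++i) {
    kmer[i] = decode_code(nodes[i].first, k);
    weight[i] = nodes[i].second;
    mark[i] = g.ref_canon.count(nodes[i].first) > 0;
  }
  return DataFrame::create(_["kmer"] = kmer, _["weight"] = weight,
                           _["ref_mark"] = mark);
}

struct WalkState {
  std::string seq;
  std::vector<int> weights;     // per node along the walk
  std::vector<char> marks;      // per node: reference-anchored
};

// One greedy extension step. Returns true if extended.
// A node below min_weight is still walkable when it is reference-marked:
// one read plus exact reference agreement cannot be a sequencing error.
static bool step(const DBG& g, std::unordered_set<uint64_t>& used,
                 uint64_t& cur, int min_weight, bool ref_rescue, bool right,
                 WalkState& ws) {
  const int k = g.k;
  const uint64_t mask = kmer_mask(k);
  int best_b = -1, best_w = 0;
  bool best_mark = false;
  uint64_t best_code = 0, best_canon = 0;
  for (int b = 0; b < 4; ++b) {
    uint64_t cand = right ? (((cur << 2) | (uint64_t)b) & mask)
                          : (((uint64_t)b << (2 * (k - 1))) | (cur >> 2));
    uint64_t canon = canonical_code(cand, k);
    if (used.count(canon)) continue;
    auto it = g.w.find(canon);
    if (it == g.w.end()) continue;
    bool mark = g.ref_canon.count(canon) > 0;
    if (it->second < min_weight && !(ref_rescue && mark)) continue;
    // highest weight; ties toward reference-marked, then lexicographically
    // smallest base (b ascending covers A<C<G<T)
    if (it->second > best_w || (it->second == best_w && mark && !best_mark)) {
      best_b = b; best_w = it->second; best_mark = mark;
      best_code = cand; best_canon = canon;
    }
  }
  if (best_b < 0) return false;
  used.insert(best_canon);
  if (right) ws.seq.push_back(CODE_BASE[best_b]);
  else ws.seq.insert(ws.seq.begin(), CODE_BASE[best_b]);
  if (right) { ws.weights.push_back(best_w); ws.marks.push_back(best_mark ? 1 : 0); }
  else { ws.weights.insert(ws.weights.begin(), best_w);
         ws.marks.insert(ws.marks.begin(), best_mark ? 1 : 0); }
  cur = best_code;
  return true;
}

// Assemble contigs from screened reads guided by the reference.
// Returns contigs (reference strand), mean node weight, and anchor counts.
// soft_boundary: emitted sequence is trimmed to at most this many bases
// beyond the outermost reference-anchored node of the walk.
// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, CharacterVector ref, int k,
                  int min_weight, int soft_boundary, int max_contigs,
                  bool ref_rescue) {
  DBG g;
  build_dbg(g, reads, ref, k);

  // seeds: reference-marked nodes, heaviest first, code ascending for ties
  std::vector<std::pair<uint64_t, int> > seeds;
  for (auto& kv : g.w) {
    if ((kv.second >= min_weight || ref_rescue) && g.ref_canon.count(kv.first))
      seeds.push_back(std::make_pair(kv.first, kv.second));
  }
  std::sort(seeds.begin(), seeds.end(),
            [](const std::pair<uint64_t, int>& a, const std::pair<uint64_t, int>& b) {
              if (a.second != b.second) return a.second > b.second;
              return a.first < b.first;
            });

  std::unordered_set<uint64_t> used;
  std::vector<std::string> contigs;
  std::vector<double> supports;
  std::vector<int> n_nodes;

  for (auto& sd : seeds) {
    if ((int)contigs.size() >= max_contigs) break;
    if (used.count(sd.first)) continue;
    // orient the seed to the reference strand
    uint64_t fwd = sd.first;
    if (!g.ref_fwd.count(fwd)) {
      uint64_t rc = revcomp_code(fwd, g.k);
      if (g.ref_fwd.count(rc)) fwd = rc;
    }
    WalkState ws;
    ws.seq = decode_code(fwd, g.k);
    ws.weights.push_back(sd.second);
    ws.marks.push_back(1);
    used.insert(sd.first);
    uint64_t cur = fwd;
    while (step(g, used, cur, min_weight, ref_rescue, true, ws)) {}
    cur = fwd;
    while (step(g, used, cur, min_weight, ref_rescue, false, ws)) {}
    // soft boundary: trim to outermost reference-anchored node +/- bound
    int first_mark = -1, last_mark = -1;
    for (size_t i = 0; i < ws.marks.size(); ++i)
      if (ws.marks[i]) { if (first_mark < 0) first_mark = (int)i; last_mark = (int)i; }
    if (first_mark < 0) continue;  // unanchored walk: not emitted
    int lo = std::max(0, first_mark - soft_boundary);
    int hi = std::min((int)ws.marks.size() - 1, last_mark + soft_boundary);
    std::string seq = ws.seq.substr((size_t)lo, (size_t)(hi - lo + 1) + (size_t)(g.k - 1));
    double wsum = 0;
    for (int i = lo; i <= hi; ++i) wsum += ws.weights[(size_t)i];
    contigs.push_back(seq);
    supports.push_back(wsum / (double)(hi - lo + 1));
    n_nodes.push_back(hi - lo + 1);
  }

  // longest first; ties by sequence for total determinism
  std::vector<size_t> ord(contigs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (contigs[a].size() != contigs[b].size())
      return contigs[a].size() > contigs[b].size();
    return contigs[a] < contigs[b];
  });
  CharacterVector cseq(ord.size());
  NumericVector csup(ord.size());
  IntegerVector cn(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    cseq[i] = contigs[ord[i]];
    csup[i] = supports[ord[i]];
    cn[i] = n_nodes[ord[i]];
  }
  return List::create(_["contig"] = cseq, _["support"] = csup,
                      _["n_nodes"] = cn);
}
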