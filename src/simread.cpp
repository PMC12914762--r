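// Read-pair simulator and per-site mutator. All randomness flows through
// R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <string>
#include "kmer_util.h"

using namespace Rcpp;

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': case 'a': out[i] = 'T'; break;
      case 'C': case 'c': out[i] = 'G'; break;
      case 'G': case 'g': out[i] = 'C'; break;
      case 'T': case 't': out[i] = 'A'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

static void add_errors(std::string& s, double p_err) {
  if (p_err <= 0) return;
  for (size_t i = 0; i < s.size(); ++i) {
    if (unif_rand() < p_err) {
      int b = base_code(s[i]);
      if (b < 0) continue;
      int nb = (b + 1 + (int)(unif_rand() * 3.0)) & 3;  // a different base
      s[i] = CODE_BASE[nb];
    }
  }
}

// Uniform-fragment paired-end simulator: fragment starts uniform over the
// genome, lengths normal(insert_mean, insert_sd) clamped to
// [read_len, genome length], source strand random, per-base substitution
// errors at p_err.
// [[Rcpp::export]]
List cpp_sim_reads(std::string genome, int n_pairs, int read_len,
                   double insert_mean, double insert_sd, double p_err) {
  const int L = (int)genome.size();
  if (L < (int)insert_mean) stop("genome shorter than the mean insert size");
  if (L < read_len) stop("genome shorter than the read length");
  CharacterVector r1(n_pairs), r2(n_pairs);
  IntegerVector start(n_pairs), frag_len(n_pairs);
  LogicalVector minus(n_pairs);
  for (int i = 0; i < n_pairs; ++i) {
    int ins = (int)(R::rnorm(insert_mean, insert_sd) + 0.5);
    if (ins < read_len) ins = read_len;
    if (ins > L) ins = L;
    int s = (int)(unif_rand() * (double)(L - ins + 1));
    if (s > L - ins) s = L - ins;
    std::string left = genome.substr((size_t)s, (size_t)read_len);
    std::string right = revcomp_str(genome.substr((size_t)(s + ins - read_len),
                                                  (size_t)read_len));
    bool neg = unif_rand() < 0.5;  // fragment sequenced from the minus strand
    std::string a = neg ? right : left;
    std::string b = neg ? left : right;
    add_errors(a, p_err);
    add_errors(b, p_err);
    r1[i] = a; r2[i] = b;
    start[i] = s + 1;  // 1-based fragment start, reported for ground truth
    frag_len[i] = ins;
    minus[i] = neg;
  }
  return List::create(_["r1"] = r1, _["r2"] = r2, _["start"] = start,
                      _["frag_len"] = frag_len, _["minus"] = minus);
}

// Substitute each site independently with probability `divergence` to a
// uniformly chosen different base.
// [[Rcpp::export]]
CharacterVector cpp_mutate(CharacterVector seqs, double divergence) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (divergence >= 1.0) {
      for (size_t j = 0; j < s.size(); ++j) {
        int b = base_code(s[j]);
        if (b < 0) continue;
        int nb = (b + 1 + (int)(unif_rand() * 3.0)) & 3;
        s[j] = CODE_BASE[nb];
      }
    } else {
      add_errors(s, divergence);
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_encode_kmer(std::string seq) {
  uint64_t code;
  int k = (int)seq.size();
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  if (!encode_string(seq, k, &code)) stop("sequence contains a non-ACGT base");
  return (double)code;
}

// [[Rcpp::export]]
std::string cpp_decode_kmer(double value, int k) {
  return decode_code((uint64_t)value, k);
}
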