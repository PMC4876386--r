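#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  default:  return 'N';
  }
}

std::string revcomp_one(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_one(s);
  }
  return out;
}

// Quality/N trimming. Order: strip leading/trailing maximal N runs, then
// drop the longest 3' suffix whose bases are all below min_phred, then
// apply the length filter.
// [[Rcpp::export]]
List cpp_trim_reads(CharacterVector seqs, CharacterVector quals,
                    int min_phred, int min_len, bool trim_n) {
  R_xlen_t n = seqs.size();
  CharacterVector out_seq(n), out_qual(n);
  LogicalVector keep(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int lo = 0, hi = (int)s.size();
    if (trim_n) {
      while (lo < hi && s[lo] == 'N') ++lo;
      while (hi > lo && s[hi - 1] == 'N') --hi;
    }
    while (hi > lo && ((int)q[hi - 1] - 33) < min_phred) --hi;
    int len = hi - lo;
    keep[i] = (len >= min_len);
    out_seq[i] = s.substr(lo, len);
    out_qual[i] = q.substr(lo, len);
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["keep"] = keep);
}
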