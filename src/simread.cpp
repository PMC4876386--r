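#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Draw Phred+33 quality strings from a per-position quality histogram.
// cum: (n_levels x read_len) column-wise cumulative probabilities;
// qvals: Phred value of each level. Uses the R RNG.
// [[Rcpp::export]]
CharacterVector cpp_sample_quals(NumericMatrix cum, IntegerVector qvals,
                                 int n_reads) {
  int L = cum.ncol(), nl = cum.nrow();
  CharacterVector out(n_reads);
  std::string q(L, '!');
  for (int r = 0; r < n_reads; ++r) {
    for (int p = 0; p < L; ++p) {
      double u = unif_rand();
      int lev = 0;
      while (lev < nl - 1 && u > cum(lev, p)) ++lev;
      q[p] = (char)(33 + qvals[lev]);
    }
    out[r] = q;
  }
  return out;
}

// Substitute each base with probability 10^(-q/10) (its Phred error
// probability) to a uniformly chosen different base. Uses the R RNG.
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector seqs, CharacterVector quals) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      double perr = std::pow(10.0, -((int)q[p] - 33) / 10.0);
      if (unif_rand() < perr) {
        char cur = s[p];
        char sub;
        do {
          sub = bases[(int)(unif_rand() * 4.0) & 3];
        } while (sub == cur);
        s[p] = sub;
      }
    }
    out[i] = s;
  }
  return out;
}
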