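#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

// 2-bit k-mer encoding, k <= 15 so a canonical k-mer fits a signed 32-bit
// integer. Canonical form = min(code, code of reverse complement). K-mers
// containing non-ACGT characters are skipped.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// enumerate canonical k-mer codes of s (with multiplicity)
static void canon_kmers(const std::string &s, int k, std::vector<int> &out) {
  int L = (int)s.size();
  if (L < k) return;
  int fwd = 0, rev = 0, valid = 0;
  int mask = (1 << (2 * k)) - 1;
  int shift = 2 * (k - 1);
  for (int i = 0; i < L; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | c) & mask;
    rev = (rev >> 2) | ((3 - c) << shift);
    if (++valid >= k) out.push_back(std::min(fwd, rev));
  }
}

// [[Rcpp::export]]
IntegerVector cpp_kmer_set(CharacterVector seqs, int k) {
  std::vector<int> all;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    canon_kmers(s, k, all);
  }
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());
  return wrap(all);
}

// For each read, the fraction of its canonical k-mer positions present in
// each category set; category = argmax fraction if >= min_frac (ties break
// to the earlier category in the list order), else 0 (unclassified).
// [[Rcpp::export]]
List cpp_classify_reads(CharacterVector seqs, List sets, int k,
                        double min_frac) {
  int ncat = sets.size();
  std::vector<std::unordered_set<int> > idx(ncat);
  for (int c = 0; c < ncat; ++c) {
    IntegerVector v = sets[c];
    idx[c].insert(v.begin(), v.end());
  }
  R_xlen_t n = seqs.size();
  IntegerVector cat(n);
  NumericMatrix frac(ncat, n);
  std::vector<int> km;
  for (R_xlen_t i = 0; i < n; ++i) {
    km.clear();
    std::string s = as<std::string>(seqs[i]);
    canon_kmers(s, k, km);
    int total = (int)km.size();
    int best = -1;
    double best_f = -1.0;
    for (int c = 0; c < ncat; ++c) {
      double f = 0.0;
      if (total > 0) {
        int hits = 0;
        for (size_t j = 0; j < km.size(); ++j)
          if (idx[c].count(km[j])) ++hits;
        f = (double)hits / total;
      }
      frac(c, i) = f;
      if (f > best_f + 1e-12) { best_f = f; best = c; }
    }
    cat[i] = (total > 0 && best_f >= min_frac - 1e-12) ? best + 1 : 0;
  }
  return List::create(_["category"] = cat, _["fractions"] = frac);
}
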