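#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

std::string revcomp_one(const std::string &s);

// Paired-end overlap merging. The reverse mate is reverse-complemented and
// all relative offsets are scanned; an offset is a candidate when the
// overlap length is >= min_overlap and the mismatch fraction (N never
// matches) is <= max_diff. The longest candidate wins; ties go to fewer
// mismatches, then to the smaller offset. In the overlapped region the
// higher-quality base is emitted (mate 1 on quality ties) with the maximum
// of the two qualities.
//
// Offset d places reverse-complemented mate 2 so that its position j aligns
// with mate-1 position j + d.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_diff) {
  R_xlen_t n = seq1.size();
  LogicalVector merged(n);
  CharacterVector mseq(n), mqual(n);
  IntegerVector offset(n), ov_len(n), mism(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(seq1[i]);
    std::string q1 = as<std::string>(qual1[i]);
    std::string s2 = revcomp_one(as<std::string>(seq2[i]));
    std::string q2 = as<std::string>(qual2[i]);
    std::reverse(q2.begin(), q2.end());
    int L1 = (int)s1.size(), L2 = (int)s2.size();
    int best_len = -1, best_mis = 0, best_d = 0;
    for (int d = -(L2 - 1); d <= L1 - 1; ++d) {
      int lo = std::max(0, d), hi = std::min(L1, d + L2);
      int L = hi - lo;
      if (L < min_overlap) continue;
      int m = 0;
      for (int p = lo; p < hi; ++p) {
        char a = s1[p], b = s2[p - d];
        if (a != b || a == 'N' || b == 'N') ++m;
      }
      if ((double)m > max_diff * L + 1e-9) continue;
      if (L > best_len || (L == best_len && m < best_mis)) {
        best_len = L; best_mis = m; best_d = d;
      }
    }
    if (best_len < 0) { merged[i] = false; continue; }
    merged[i] = true;
    int d = best_d;
    int lo = std::min(0, d), hi = std::max(L1, d + L2);
    std::string os, oq;
    os.reserve(hi - lo); oq.reserve(hi - lo);
    for (int p = lo; p < hi; ++p) {
      bool in1 = (p >= 0 && p < L1);
      bool in2 = (p >= d && p < d + L2);
      if (in1 && in2) {
        char b1 = s1[p], b2 = s2[p - d];
        char c1 = q1[p], c2 = q2[p - d];
        os.push_back(c2 > c1 ? b2 : b1);
        oq.push_back(std::max(c1, c2));
      } else if (in1) {
        os.push_back(s1[p]); oq.push_back(q1[p]);
      } else {
        os.push_back(s2[p - d]); oq.push_back(q2[p - d]);
      }
    }
    mseq[i] = os; mqual[i] = oq;
    offset[i] = best_d; ov_len[i] = best_len; mism[i] = best_mis;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq,
                      _["qual"] = mqual, _["offset"] = offset,
                      _["overlap"] = ov_len, _["mismatches"] = mism);
}
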