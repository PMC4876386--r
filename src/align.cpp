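#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <set>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

std::string revcomp_one(const std::string &s);

static inline int base2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// plain (same-strand) k-mer codes with positions; k-mers spanning non-ACGT skipped
static void kmer_pos(const std::string &s, int k,
                     std::vector<std::pair<int,int> > &out) {
  int L = (int)s.size();
  if (L < k) return;
  int code = 0, valid = 0;
  int mask = (1 << (2 * k)) - 1;
  for (int i = 0; i < L; ++i) {
    int c = base2(s[i]);
    if (c < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | c) & mask;
    if (++valid >= k) out.push_back(std::make_pair(code, i - k + 1));
  }
}

// ungapped alignment of a and b on diagonal d (b position = a position + d);
// returns overlap length and match count (N never matches)
static inline void diag_stats(const std::string &a, const std::string &b,
                              int d, int &len, int &matches) {
  int La = (int)a.size(), Lb = (int)b.size();
  int lo = std::max(0, -d), hi = std::min(La, Lb - d);
  len = hi - lo; matches = 0;
  for (int i = lo; i < hi; ++i) {
    char x = a[i], y = b[i + d];
    if (x == y && x != 'N') ++matches;
  }
}

static inline int diag_len(int La, int Lb, int d) {
  return std::min(La, Lb - d) - std::max(0, -d);
}

// diagonals are offset by +MAXLEN so candidate keys stay non-negative
#define DIAG_BIAS 0x100000LL

// Greedy incremental clustering. Input sequences must be pre-sorted by
// length descending (stable); each sequence joins the earliest-founded
// cluster whose representative aligns on some ungapped diagonal at
// identity >= min_id (%) over an overlap >= min_cov of the shorter
// sequence, else founds a new cluster. The word filter only proposes
// candidate (representative, diagonal) pairs; with the default word = 11 it
// is lossless for identity thresholds >= 95% and overlaps >= 28 nt.
// [[Rcpp::export]]
IntegerVector cpp_cluster_greedy(CharacterVector seqs, double min_id,
                                 double min_cov, int word) {
  R_xlen_t n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> reps;
  std::unordered_map<int, std::vector<std::pair<int,int> > > index; // kmer -> (rep, pos)
  std::vector<std::pair<int,int> > km;
  std::vector<long long> cand;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    km.clear();
    kmer_pos(s, word, km);
    // candidate (rep, diagonal) keys; sorting gives founding order first
    cand.clear();
    for (size_t j = 0; j < km.size(); ++j) {
      std::unordered_map<int, std::vector<std::pair<int,int> > >::iterator it =
        index.find(km[j].first);
      if (it == index.end()) continue;
      const std::vector<std::pair<int,int> > &hits = it->second;
      for (size_t h = 0; h < hits.size(); ++h)
        cand.push_back(((long long)hits[h].first << 22) +
                       (hits[h].second - km[j].second) + DIAG_BIAS);
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    int chosen = 0;
    int Ls = (int)s.size();
    for (size_t c = 0; c < cand.size(); ++c) {
      int rid = (int)(cand[c] >> 22);
      int d = (int)(cand[c] & 0x3FFFFFLL) - (int)DIAG_BIAS;
      const std::string &rep = reps[rid];
      int shorter = std::min(Ls, (int)rep.size());
      int len = diag_len(Ls, (int)rep.size(), d);
      if (len <= 0 || (double)len < min_cov * shorter - 1e-9) continue;
      int len2, matches;
      diag_stats(s, rep, d, len2, matches);
      if (100.0 * matches < min_id * (double)len - 1e-9) continue;
      chosen = rid + 1;
      break;
    }
    if (chosen == 0) {
      reps.push_back(s);
      int rid = (int)reps.size() - 1;
      for (size_t j = 0; j < km.size(); ++j)
        index[km[j].first].push_back(std::make_pair(rid, km[j].second));
      chosen = rid + 1;
    }
    assign[i] = chosen;
  }
  return assign;
}

// Seed-and-extend best-hit mapping of queries against targets. Candidate
// (target, diagonal) pairs come from shared seed_k-mers (both query strands
// when both_strands); each candidate is scored by ungapped identity over
// the diagonal overlap. Coverage is overlap / query length (or / shorter
// sequence length when cov_on_shorter). The best qualifying hit wins:
// highest identity, then longer overlap, then smallest target index, then
// '+' strand. Identity ties are compared exactly on integer cross products.
// [[Rcpp::export]]
DataFrame cpp_map_best_hit(CharacterVector queries, CharacterVector targets,
                           double min_id, double min_cov, int seed_k,
                           bool both_strands, bool cov_on_shorter) {
  int nt = targets.size();
  std::vector<std::string> tgt(nt);
  std::unordered_map<int, std::vector<std::pair<int,int> > > index;
  std::vector<std::pair<int,int> > km;
  for (int t = 0; t < nt; ++t) {
    tgt[t] = as<std::string>(targets[t]);
    km.clear();
    kmer_pos(tgt[t], seed_k, km);
    for (size_t j = 0; j < km.size(); ++j)
      index[km[j].first].push_back(std::make_pair(t, km[j].second));
  }
  R_xlen_t nq = queries.size();
  IntegerVector target(nq), matches(nq), aln_len(nq);
  NumericVector identity(nq), coverage(nq);
  CharacterVector strand(nq);
  for (R_xlen_t i = 0; i < nq; ++i) {
    std::string fwd = as<std::string>(queries[i]);
    int best_t = -1, best_m = 0, best_l = 0;
    char best_s = '+';
    double best_cov = 0.0;
    int nstr = both_strands ? 2 : 1;
    std::vector<long long> cand;
    for (int si = 0; si < nstr; ++si) {
      std::string q = (si == 0) ? fwd : revcomp_one(fwd);
      km.clear();
      kmer_pos(q, seed_k, km);
      cand.clear();
      for (size_t j = 0; j < km.size(); ++j) {
        std::unordered_map<int, std::vector<std::pair<int,int> > >::iterator it =
          index.find(km[j].first);
        if (it == index.end()) continue;
        const std::vector<std::pair<int,int> > &hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h)
          cand.push_back(((long long)hits[h].first << 22) +
                         (hits[h].second - km[j].second) + DIAG_BIAS);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      int Lq = (int)q.size();
      for (size_t c = 0; c < cand.size(); ++c) {
        int t = (int)(cand[c] >> 22);
        int d = (int)(cand[c] & 0x3FFFFFLL) - (int)DIAG_BIAS;
        int Lt = (int)tgt[t].size();
        int base = cov_on_shorter ? std::min(Lq, Lt) : Lq;
        int len = diag_len(Lq, Lt, d);
        if (len <= 0) continue;
        double cov = (double)len / base;
        if (cov < min_cov - 1e-9) continue;
        int len2, m;
        diag_stats(q, tgt[t], d, len2, m);
        if (100.0 * m < min_id * (double)len - 1e-9) continue;
        // compare identity m/len vs best_m/best_l exactly
        long long lhs = (long long)m * best_l;
        long long rhs = (long long)best_m * len;
        bool better = false;
        if (best_t < 0 || lhs > rhs) better = true;
        else if (lhs == rhs) {
          if (len > best_l) better = true;
          else if (len == best_l && t < best_t) better = true;
        }
        if (better) {
          best_t = t; best_m = m; best_l = len;
          best_s = (si == 0) ? '+' : '-';
          best_cov = cov;
        }
      }
    }
    if (best_t < 0) {
      target[i] = 0; identity[i] = NA_REAL; coverage[i] = NA_REAL;
      matches[i] = 0; aln_len[i] = 0; strand[i] = NA_STRING;
    } else {
      target[i] = best_t + 1;
      matches[i] = best_m; aln_len[i] = best_l;
      identity[i] = 100.0 * best_m / best_l;
      coverage[i] = best_cov;
      strand[i] = std::string(1, best_s);
    }
  }
  return DataFrame::create(_["target"] = target, _["identity"] = identity,
                           _["coverage"] = coverage, _["matches"] = matches,
                           _["aln_len"] = aln_len, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
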