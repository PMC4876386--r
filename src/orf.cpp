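#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

std::string revcomp_one(const std::string &s);

static inline bool is_stop(const std::string &s, int p) {
  char a = s[p], b = s[p + 1], c = s[p + 2];
  if (a != 'T') return false;
  if (b == 'A' && (c == 'A' || c == 'G')) return true;   // TAA, TAG
  if (b == 'G' && c == 'A') return true;                 // TGA
  return false;
}

struct Frag { int read; char strand; int frame; int start; int end; };

// scan one oriented sequence; coordinates are on the oriented string
static void scan_frames(const std::string &s, int read, char strand,
                        int min_len, std::vector<Frag> &frags,
                        std::vector<std::string> &seqs) {
  int L = (int)s.size();
  for (int f = 0; f < 3; ++f) {
    int run_start = f;
    int p = f;
    for (; p + 2 < L; p += 3) {
      if (is_stop(s, p)) {
        if (p - run_start >= min_len) {
          frags.push_back(Frag{read, strand, f, run_start, p});
          seqs.push_back(s.substr(run_start, p - run_start));
        }
        run_start = p + 3;
      }
    }
    // p = first incomplete codon position; run ends at p (codon boundary)
    if (p - run_start >= min_len) {
      frags.push_back(Frag{read, strand, f, run_start, p});
      seqs.push_back(s.substr(run_start, p - run_start));
    }
  }
}

// Maximal stop-free codon stretches >= min_len nt over all six frames.
// Coordinates are 0-based half-open on the original read; for '-' strand
// fragments the sequence is the reverse-complement stretch and start/end
// are mapped back to read coordinates.
// [[Rcpp::export]]
DataFrame cpp_predict_fragments(CharacterVector reads, int min_len) {
  std::vector<Frag> frags;
  std::vector<std::string> seqs;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    scan_frames(s, (int)i + 1, '+', min_len, frags, seqs);
    std::string rc = revcomp_one(s);
    size_t before = frags.size();
    scan_frames(rc, (int)i + 1, '-', min_len, frags, seqs);
    int L = (int)s.size();
    for (size_t j = before; j < frags.size(); ++j) {
      int st = frags[j].start, en = frags[j].end;
      frags[j].start = L - en;
      frags[j].end = L - st;
    }
  }
  int n = (int)frags.size();
  IntegerVector read(n), frame(n), start(n), end(n);
  CharacterVector strand(n), seq(n);
  for (int j = 0; j < n; ++j) {
    read[j] = frags[j].read;
    strand[j] = std::string(1, frags[j].strand);
    frame[j] = frags[j].frame;
    start[j] = frags[j].start;
    end[j] = frags[j].end;
    seq[j] = seqs[j];
  }
  return DataFrame::create(_["read"] = read, _["strand"] = strand,
                           _["frame"] = frame, _["start"] = start,
                           _["end"] = end, _["seq"] = seq,
                           _["stringsAsFactors"] = false);
}
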