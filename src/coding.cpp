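#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Hexamer coding-potential scoring: stride-3 (codon-aligned) hexamer log-odds,
// composition-controlled against the record's own mononucleotide frequencies,
// decomposed into maximal scoring subsequences (Ruzzo-Tompa) per frame/strand.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Seg { int start, end; double score; };

// Ruzzo-Tompa maximal scoring subsequence decomposition.
// x: per-position scores; returns maximal segments (0-based, inclusive).
static std::vector<Seg> ruzzo_tompa(const std::vector<double>& x) {
  struct Item { int start, end; double L, R; };
  std::vector<Item> I;
  double cum = 0.0;
  for (int i = 0; i < (int) x.size(); ++i) {
    double s = x[i];
    cum += s;
    if (s <= 0) continue;
    Item k{ i, i, cum - s, cum };
    while (true) {
      // rightmost item j with L_j < L_k
      int j = (int) I.size() - 1;
      while (j >= 0 && I[j].L >= k.L) --j;
      if (j < 0 || I[j].R >= k.R) { I.push_back(k); break; }
      // extend I_j through k, drop items after j, re-test
      k.start = I[j].start;
      k.L = I[j].L;
      I.resize(j);
    }
  }
  std::vector<Seg> out;
  out.reserve(I.size());
  for (const auto& it : I) out.push_back(Seg{ it.start, it.end, it.R - it.L });
  return out;
}

// Exposed for oracle tests: maximal scoring segments of a score vector.
// Returns 1-based inclusive [start, end] and segment scores.
// [[Rcpp::export(name = ".cpp_max_scoring_segments")]]
DataFrame cpp_max_scoring_segments(const NumericVector& scores) {
  std::vector<double> x(scores.begin(), scores.end());
  std::vector<Seg> segs = ruzzo_tompa(x);
  IntegerVector st(segs.size()), en(segs.size());
  NumericVector sc(segs.size());
  for (size_t i = 0; i < segs.size(); ++i) {
    st[i] = segs[i].start + 1;
    en[i] = segs[i].end + 1;
    sc[i] = segs[i].score;
  }
  return DataFrame::create(_["start"] = st, _["end"] = en, _["score"] = sc);
}

static const double BREAK_SCORE = -1e12; // hexamers touching N split segments

// Sum of predicted coding bases over one strand (3 frames) of seq.
static double strand_coding_bases(const std::string& seq,
                                  const std::vector<double>& adj_scores,
                                  double threshold) {
  const int n = (int) seq.size();
  double total = 0.0;
  std::vector<double> frame_scores;
  for (int off = 0; off < 3; ++off) {
    frame_scores.clear();
    for (int p = off; p + 6 <= n; p += 3) {
      int code = 0;
      bool ok = true;
      for (int j = 0; j < 6; ++j) {
        int b = base_code(seq[p + j]);
        if (b < 0) { ok = false; break; }
        code = (code << 2) | b;
      }
      frame_scores.push_back(ok ? adj_scores[code] : BREAK_SCORE);
    }
    if (frame_scores.empty()) continue;
    std::vector<Seg> segs = ruzzo_tompa(frame_scores);
    for (const auto& s : segs) {
      if (s.score >= threshold)
        total += 3.0 * (s.end - s.start) + 6.0; // bases spanned by the hexamers
    }
  }
  return total;
}

static std::string revcomp(const std::string& seq) {
  std::string rc(seq.size(), 'N');
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base_code(seq[seq.size() - 1 - i]);
    rc[i] = (b < 0) ? 'N' : "TGCA"[b];
  }
  return rc;
}

// Total predicted coding bases for a record.
// scores: 4096 trained log-odds; train_log_base: log mononucleotide
// frequencies of the training set (the trained null); both_strands: add the
// reverse complement's three frames.
// [[Rcpp::export(name = ".cpp_predicted_coding_length")]]
double cpp_predicted_coding_length(const std::string& seq,
                                   const NumericVector& scores,
                                   const NumericVector& train_log_base,
                                   double threshold, bool both_strands) {
  if (scores.size() != 4096) stop("scores must have 4096 entries");
  if ((int) seq.size() < 6) return 0.0;
  // record mononucleotide null (pseudocount 1 per base)
  double cnt[4] = { 1.0, 1.0, 1.0, 1.0 };
  double tot = 4.0;
  for (char c : seq) {
    int b = base_code(c);
    if (b >= 0) { cnt[b] += 1.0; tot += 1.0; }
  }
  double delta[4];
  for (int b = 0; b < 4; ++b)
    delta[b] = train_log_base[b] - std::log(cnt[b] / tot);
  // composition-adjusted score per hexamer
  std::vector<double> adj(4096);
  for (int h = 0; h < 4096; ++h) {
    double a = scores[h];
    int code = h;
    for (int j = 0; j < 6; ++j) { a += delta[code & 3]; code >>= 2; }
    adj[h] = a;
  }
  double total = strand_coding_bases(seq, adj, threshold);
  if (both_strands) total += strand_coding_bases(revcomp(seq), adj, threshold);
  return total;
}

// Stride-3 frame-0 hexamer counts of a set of sequences (for table training).
// [[Rcpp::export(name = ".cpp_hexamer_counts")]]
NumericVector cpp_hexamer_counts(const CharacterVector& seqs) {
  NumericVector out(4096);
  for (int r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    const int n = (int) LENGTH(STRING_ELT(seqs, r));
    for (int p = 0; p + 6 <= n; p += 3) {
      int code = 0;
      bool ok = true;
      for (int j = 0; j < 6; ++j) {
        int b = base_code(s[p + j]);
        if (b < 0) { ok = false; break; }
        code = (code << 2) | b;
      }
      if (ok) out[code] += 1.0;
    }
  }
  return out;
}
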