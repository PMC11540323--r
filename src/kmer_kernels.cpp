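#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else (incl. N) = -1
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".cpp_count_canonical")]]
IntegerVector cpp_count_canonical(const std::string& seq, int k,
                                  const IntegerVector& colmap, int ncol) {
  // colmap: length 4^k, 0-based column for each noncanonical k-mer code
  IntegerVector out(ncol);
  const int n = (int) seq.size();
  if (n < k) return out;
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  uint32_t code = 0;
  int valid = 0; // length of current run of valid bases
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t) b) & mask;
    if (++valid >= k) out[colmap[code]]++;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_count_matrix")]]
IntegerMatrix cpp_count_matrix(const CharacterVector& seqs, int k,
                               const IntegerVector& colmap, int ncol) {
  const int nr = seqs.size();
  IntegerMatrix out(nr, ncol);
  for (int r = 0; r < nr; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    const int n = (int) LENGTH(STRING_ELT(seqs, r));
    const uint32_t mask = (1u << (2 * k)) - 1u;
    uint32_t code = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++valid >= k) out(r, colmap[code])++;
    }
  }
  return out;
}

// Distinct noncanonical k-mers / total valid windows; -1 if no valid windows.
// [[Rcpp::export(name = ".cpp_unique_kmer_fraction")]]
double cpp_unique_kmer_fraction(const std::string& seq, int k) {
  const int n = (int) seq.size();
  if (n < k || k < 1 || k > 15) return -1.0;
  const size_t nslots = ((size_t)1) << (2 * k);
  std::vector<bool> seen(nslots, false);
  const uint32_t mask = (uint32_t)(nslots - 1);
  uint32_t code = 0;
  int valid = 0;
  long total = 0, distinct = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t) b) & mask;
    if (++valid >= k) {
      ++total;
      if (!seen[code]) { seen[code] = true; ++distinct; }
    }
  }
  if (total == 0) return -1.0;
  return (double) distinct / (double) total;
}

// Per-base GC over A/C/G/T only; returns c(gc_count, acgt_count)
// [[Rcpp::export(name = ".cpp_gc_counts")]]
NumericVector cpp_gc_counts(const std::string& seq) {
  long gc = 0, tot = 0;
  for (char c : seq) {
    int b = base_code(c);
    if (b < 0) continue;
    ++tot;
    if (b == 1 || b == 2) ++gc;
  }
  return NumericVector::create((double) gc, (double) tot);
}
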