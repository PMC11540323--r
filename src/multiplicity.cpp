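#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// Whole-read-set canonical k-mer multiplicity table (k odd, <= 31).
// Codes are 2-bit packed into 64 bits; canonical code = min(code, revcomp code).

struct MultTable {
  int k;
  uint32_t cap;                 // count ceiling
  double total_windows;         // valid windows tallied (pre-cap)
  double cap_losses;            // increments lost to the ceiling
  std::unordered_map<uint64_t, uint32_t> counts;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export(name = ".cpp_mt_new")]]
SEXP cpp_mt_new(int k, double cap) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (k % 2 == 0) stop("k must be odd (avoids palindromic canonical ambiguity)");
  MultTable* t = new MultTable();
  t->k = k;
  t->cap = (uint32_t) cap;
  t->total_windows = 0.0;
  t->cap_losses = 0.0;
  XPtr<MultTable> p(t, true);
  return p;
}

// [[Rcpp::export(name = ".cpp_mt_add")]]
void cpp_mt_add(SEXP ptr, const CharacterVector& seqs) {
  XPtr<MultTable> t(ptr);
  const int k = t->k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  for (int r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    const int n = (int) LENGTH(STRING_ELT(seqs, r));
    uint64_t code = 0, rc = 0;
    int valid = 0;
    const int shift = 2 * (k - 1);
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; code = 0; rc = 0; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++valid >= k) {
        uint64_t canon = std::min(code, rc);
        t->total_windows += 1.0;
        uint32_t& c = t->counts[canon];
        if (c < t->cap) ++c; else t->cap_losses += 1.0;
      }
    }
  }
}

// Lower median multiplicity per sequence; NA for sequences without valid windows.
// [[Rcpp::export(name = ".cpp_mt_median")]]
IntegerVector cpp_mt_median(SEXP ptr, const CharacterVector& seqs) {
  XPtr<MultTable> t(ptr);
  const int k = t->k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  IntegerVector out(seqs.size());
  std::vector<uint32_t> vals;
  for (int r = 0; r < seqs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    const int n = (int) LENGTH(STRING_ELT(seqs, r));
    vals.clear();
    uint64_t code = 0, rc = 0;
    int valid = 0;
    const int shift = 2 * (k - 1);
    for (int i = 0; i < n; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; code = 0; rc = 0; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      rc = (rc >> 2) | (((uint64_t)(3 - b)) << shift);
      if (++valid >= k) {
        uint64_t canon = std::min(code, rc);
        auto it = t->counts.find(canon);
        vals.push_back(it == t->counts.end() ? 0u : it->second);
      }
    }
    if (vals.empty()) { out[r] = NA_INTEGER; continue; }
    size_t m = (vals.size() - 1) / 2; // lower median
    std::nth_element(vals.begin(), vals.begin() + m, vals.end());
    out[r] = (int) vals[m];
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_mt_stats")]]
List cpp_mt_stats(SEXP ptr) {
  XPtr<MultTable> t(ptr);
  return List::create(_["k"] = t->k,
                      _["cap"] = (double) t->cap,
                      _["distinct"] = (double) t->counts.size(),
                      _["total_windows"] = t->total_windows,
                      _["cap_losses"] = t->cap_losses);
}

// Coverage histogram: multiplicity value -> number of distinct k-mers with it.
// [[Rcpp::export(name = ".cpp_mt_histogram")]]
DataFrame cpp_mt_histogram(SEXP ptr) {
  XPtr<MultTable> t(ptr);
  std::unordered_map<uint32_t, double> h;
  for (const auto& kv : t->counts) h[kv.second] += 1.0;
  std::vector<uint32_t> keys;
  keys.reserve(h.size());
  for (const auto& kv : h) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerVector cov(keys.size());
  NumericVector n(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    cov[i] = (int) keys[i];
    n[i] = h[keys[i]];
  }
  return DataFrame::create(_["multiplicity"] = cov, _["n_kmers"] = n);
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[code & 3ULL]; code >>= 2; }
  return s;
}

// Dump as (kmer string, count), sorted by code — for persistence of small tables.
// [[Rcpp::export(name = ".cpp_mt_dump")]]
DataFrame cpp_mt_dump(SEXP ptr) {
  XPtr<MultTable> t(ptr);
  std::vector<uint64_t> codes;
  codes.reserve(t->counts.size());
  for (const auto& kv : t->counts) codes.push_back(kv.first);
  std::sort(codes.begin(), codes.end());
  CharacterVector km(codes.size());
  NumericVector ct(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) {
    km[i] = decode_kmer(codes[i], t->k);
    ct[i] = (double) t->counts[codes[i]];
  }
  return DataFrame::create(_["kmer"] = km, _["count"] = ct,
                           _["stringsAsFactors"] = false);
}

// Rebuild a table from dumped (kmer, count) pairs.
// [[Rcpp::export(name = ".cpp_mt_load")]]
SEXP cpp_mt_load(int k, double cap, const CharacterVector& kmers,
                 const NumericVector& counts) {
  SEXP ptr = cpp_mt_new(k, cap);
  XPtr<MultTable> t(ptr);
  for (int i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[j]);
      if (b < 0) stop("invalid base in k-mer %d", i + 1);
      code = (code << 2) | (uint64_t) b;
    }
    uint64_t canon = std::min(code, revcomp_code(code, k));
    t->counts[canon] = (uint32_t) counts[i];
    t->total_windows += counts[i];
  }
  return ptr;
}
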