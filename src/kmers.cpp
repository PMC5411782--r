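#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; -1 for anything else.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// Enumerate canonical k-mers (lexicographic min of k-mer and reverse
// complement under A<C<G<T, which matches 2-bit numeric order) of one
// sequence with a rolling encoding; windows containing non-ACGT are skipped.
// Requires k <= 31 so the word fits in 62 bits.
template <typename F>
static void each_canonical_u64(const char* s, R_xlen_t len, int k, F f) {
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(fwd < rev ? fwd : rev);
  }
}

static std::string decode_u64(uint64_t code, int k) {
  std::string out(k, 'N');
  for (int i = k - 1; i >= 0; --i) {
    out[i] = CODE_BASE[code & 3ULL];
    code >>= 2;
  }
  return out;
}

// String fallback for 31 < k <= 63.
template <typename F>
static void each_canonical_str(const char* s, R_xlen_t len, int k, F f) {
  if (len < k) return;
  for (R_xlen_t i = 0; i + k <= len; ++i) {
    std::string fwd(k, 'N'), rev(k, 'N');
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[i + j]);
      if (c < 0) { ok = false; break; }
      fwd[j] = CODE_BASE[c];
      rev[k - 1 - j] = CODE_BASE[3 - c];
    }
    if (ok) f(fwd < rev ? fwd : rev);
  }
}

typedef std::unordered_map<uint64_t, uint32_t> CountMapU64;
typedef std::unordered_map<std::string, uint32_t> CountMapStr;

static void count_into_u64(CharacterVector seqs, int k, CountMapU64& m) {
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    each_canonical_u64(s, (R_xlen_t)LENGTH(STRING_ELT(seqs, i)), k,
                       [&](uint64_t key) { ++m[key]; });
  }
}

static void count_into_str(CharacterVector seqs, int k, CountMapStr& m) {
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    each_canonical_str(s, (R_xlen_t)LENGTH(STRING_ELT(seqs, i)), k,
                       [&](const std::string& key) { ++m[key]; });
  }
}

// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector seqs, int k) {
  std::vector<std::string> kmers;
  std::vector<double> counts;
  if (k <= 31) {
    CountMapU64 m;
    count_into_u64(seqs, k, m);
    kmers.reserve(m.size()); counts.reserve(m.size());
    for (auto& kv : m) { kmers.push_back(decode_u64(kv.first, k)); counts.push_back(kv.second); }
  } else {
    CountMapStr m;
    count_into_str(seqs, k, m);
    kmers.reserve(m.size()); counts.reserve(m.size());
    for (auto& kv : m) { kmers.push_back(kv.first); counts.push_back(kv.second); }
  }
  return List::create(_["kmer"] = wrap(kmers), _["count"] = wrap(counts));
}

// Histogram of multiplicities: element i of the result is the number of
// distinct canonical k-mers seen exactly i times.
// [[Rcpp::export]]
NumericVector cpp_kmer_hist(CharacterVector seqs, int k) {
  std::vector<double> hist;
  auto tally = [&](uint32_t mult) {
    if (mult > hist.size()) hist.resize(mult, 0.0);
    hist[mult - 1] += 1.0;
  };
  if (k <= 31) {
    CountMapU64 m;
    count_into_u64(seqs, k, m);
    for (auto& kv : m) tally(kv.second);
  } else {
    CountMapStr m;
    count_into_str(seqs, k, m);
    for (auto& kv : m) tally(kv.second);
  }
  return wrap(hist);
}

// Joint decomposition: matrix[m][c] = number of distinct canonical k-mers
// with read multiplicity m (rows 0..m_max) and assembly copy number c
// (columns 0..c_max, last column aggregating copies > c_max - 1 is handled
// by the caller-facing wrapper via the open-ended flag here).
// [[Rcpp::export]]
NumericMatrix cpp_spectra_cn(CharacterVector reads, CharacterVector assembly,
                             int k, int c_max) {
  // multiplicity -> (copy-number -> count), built sparsely then densified
  std::vector<std::unordered_map<uint32_t, double> > cells;
  uint32_t m_max = 0;
  auto add_cell = [&](uint32_t m, uint32_t c) {
    if (m > m_max) m_max = m;
    uint32_t cc = c > (uint32_t)c_max ? (uint32_t)(c_max + 1) : c;
    if (cells.size() <= m) cells.resize(m + 1);
    cells[m][cc] += 1.0;
  };
  if (k <= 31) {
    CountMapU64 rm, am;
    count_into_u64(reads, k, rm);
    count_into_u64(assembly, k, am);
    for (auto& kv : rm) {
      auto it = am.find(kv.first);
      add_cell(kv.second, it == am.end() ? 0u : it->second);
    }
    for (auto& kv : am) if (rm.find(kv.first) == rm.end()) add_cell(0u, kv.second);
  } else {
    CountMapStr rm, am;
    count_into_str(reads, k, rm);
    count_into_str(assembly, k, am);
    for (auto& kv : rm) {
      auto it = am.find(kv.first);
      add_cell(kv.second, it == am.end() ? 0u : it->second);
    }
    for (auto& kv : am) if (rm.find(kv.first) == rm.end()) add_cell(0u, kv.second);
  }
  int ncol = c_max + 2;  // copies 0..c_max plus the open-ended ">c_max" bin
  NumericMatrix out(m_max + 1, ncol);
  for (uint32_t m = 0; m < cells.size(); ++m)
    for (auto& kv : cells[m]) out(m, kv.first) = kv.second;
  return out;
}

// Sequential redundancy screen. `seqs` must already be ordered (longest
// first); `always_keep[i]` marks scaffolds above the length gate. Short
// scaffolds are dropped when at least `threshold` of their distinct k-mers
// are present in previously retained scaffolds. Returns, per scaffold, the
// keep flag, the fraction of its distinct k-mers already represented, and
// its distinct k-mer count, plus the number of distinct k-mers found only
// in removed scaffolds (unique content lost).
// [[Rcpp::export]]
List cpp_redundancy_filter(CharacterVector seqs, LogicalVector always_keep,
                           double threshold, int k) {
  R_xlen_t n = seqs.size();
  LogicalVector keep(n);
  NumericVector frac(n), nk(n);
  if (k > 31) stop("redundancy filter supports k <= 31");
  std::unordered_set<uint64_t> kept_set;
  std::vector<std::vector<uint64_t> > removed_kmers;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(seqs, i));
    std::unordered_set<uint64_t> mine;
    each_canonical_u64(s, len, k, [&](uint64_t key) { mine.insert(key); });
    double shared = 0;
    for (uint64_t key : mine) if (kept_set.count(key)) shared += 1.0;
    double f = mine.empty() ? 1.0 : shared / (double)mine.size();
    frac[i] = f;
    nk[i] = (double)mine.size();
    bool retain = always_keep[i] || f < threshold;
    keep[i] = retain;
    if (retain) {
      for (uint64_t key : mine) kept_set.insert(key);
    } else {
      removed_kmers.emplace_back(mine.begin(), mine.end());
    }
  }
  std::unordered_set<uint64_t> lost;
  for (auto& v : removed_kmers)
    for (uint64_t key : v)
      if (!kept_set.count(key)) lost.insert(key);
  return List::create(_["keep"] = keep, _["redundant_fraction"] = frac,
                      _["n_kmers"] = nk,
                      _["unique_content_lost"] = (double)lost.size());
}

// Number of distinct canonical k-mers present in `a` but absent from `b`
// (set-difference cardinality); used for QC oracles and summaries.
// [[Rcpp::export]]
double cpp_kmer_set_difference(CharacterVector a, CharacterVector b, int k) {
  if (k <= 31) {
    CountMapU64 ma, mb;
    count_into_u64(a, k, ma);
    count_into_u64(b, k, mb);
    double n = 0;
    for (auto& kv : ma) if (mb.find(kv.first) == mb.end()) n += 1.0;
    return n;
  }
  CountMapStr ma, mb;
  count_into_str(a, k, ma);
  count_into_str(b, k, mb);
  double n = 0;
  for (auto& kv : ma) if (mb.find(kv.first) == mb.end()) n += 1.0;
  return n;
}
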