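// Core primitives: canonicalization, k-mer counting, the coupled Bloom
// filter bit planes, neighbor z-scores and seed extension. These are the
// hot loops of the method; everything format-related stays in R.
#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <climits>
#include <cmath>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 0;
  }
}

// reverse complement; returns false on a non-ACGT character
static inline bool revcomp_str(const std::string &s, std::string &out) {
  const size_t n = s.size();
  out.resize(n);
  for (size_t i = 0; i < n; ++i) {
    const char c = comp_base(s[n - 1 - i]);
    if (!c) return false;
    out[i] = c;
  }
  return true;
}

// canonical form: lexicographic min of s and revcomp(s).
// Single-threaded scratch buffer: avoids one heap allocation per call in
// the neighbor/extension hot loops.
static inline bool canon_str(const std::string &s, std::string &out) {
  static std::string rc;
  if (!revcomp_str(s, rc)) return false;
  out = (rc < s) ? rc : s;
  return true;
}

// [[Rcpp::export]]
CharacterVector rc_revcomp(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string rc;
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    if (!revcomp_str(s, rc))
      stop("non-ACGT character in sequence %d: '%s'", (int)(i + 1), s.c_str());
    out[i] = rc;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector rc_canonical(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string cn;
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    if (!canon_str(s, cn))
      stop("non-ACGT character in sequence %d: '%s'", (int)(i + 1), s.c_str());
    out[i] = cn;
  }
  return out;
}

// 2-bit base codes (A=0, C=1, G=2, T=3); -1 for anything else
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// Count canonical k-mers over all k-windows made only of A/C/G/T.
// For k <= 32 windows are packed into 64-bit keys (first base in the most
// significant bits, so numeric order equals lexicographic order and the
// canonical form is the numeric min of the forward and reverse-complement
// codes); longer k falls back to string keys.
// [[Rcpp::export]]
List rc_count_kmers(CharacterVector seqs, int k) {
  if (k < 1) stop("k must be >= 1");
  if (k <= 32) {
    std::unordered_map<uint64_t, int> tab;
    const int shift = 2 * (k - 1);
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (R_xlen_t r = 0; r < seqs.size(); ++r) {
      const char *s = CHAR(STRING_ELT(seqs, r));
      const long L = (long)LENGTH(STRING_ELT(seqs, r));
      if (L < k) continue;
      uint64_t fwd = 0, rev = 0;
      long valid = 0;  // length of the current run of ACGT bases
      for (long i = 0; i < L; ++i) {
        const int c = base_code(s[i]);
        if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
        if (++valid >= k)
          ++tab[fwd < rev ? fwd : rev];
      }
    }
    const size_t n = tab.size();
    CharacterVector kmers(n);
    IntegerVector counts(n);
    std::string buf(k, 'A');
    size_t j = 0;
    for (auto &kv : tab) {
      uint64_t key = kv.first;
      for (int i = k - 1; i >= 0; --i) {
        buf[i] = CODE_BASE[key & 3ULL];
        key >>= 2;
      }
      kmers[j] = buf;
      counts[j] = kv.second;
      ++j;
    }
    return List::create(_["kmer"] = kmers, _["count"] = counts);
  }
  std::unordered_map<std::string, int> tab;
  std::string win, cn;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const std::string s = as<std::string>(seqs[r]);
    const long L = (long)s.size();
    if (L < k) continue;
    long last_bad = -1;  // most recent invalid position
    for (long i = 0; i < L; ++i) {
      if (!comp_base(s[i])) last_bad = i;
      const long start = i - k + 1;
      if (start < 0 || last_bad >= start) continue;
      win.assign(s, start, k);
      canon_str(win, cn);   // cannot fail: window validated
      ++tab[cn];
    }
  }
  const size_t n = tab.size();
  CharacterVector kmers(n);
  IntegerVector counts(n);
  size_t j = 0;
  for (auto &kv : tab) {
    kmers[j] = kv.first;
    counts[j] = kv.second;
    ++j;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}

// ---- hashing -------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// seeded FNV-1a with a final avalanche mix
static inline uint64_t str_hash(const std::string &s, uint64_t seed) {
  uint64_t h = 1469598103934665603ULL ^ splitmix64(seed);
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return splitmix64(h);
}

static inline int get_bit(const unsigned char *p, uint64_t pos) {
  return (p[pos >> 3] >> (pos & 7)) & 1;
}

static inline void set_bit(unsigned char *p, uint64_t pos, int v) {
  if (v) p[pos >> 3] |= (unsigned char)(1u << (pos & 7));
  else   p[pos >> 3] &= (unsigned char)~(1u << (pos & 7));
}

struct CbfView {
  const unsigned char *bp;
  const unsigned char *bm;
  uint64_t m;
  int h;
  uint64_t s1, s2;
};

// double hashing: position of count bit i for key `s`
static inline void key_positions(const std::string &s, const CbfView &f,
                                 std::vector<uint64_t> &pos) {
  const uint64_t a = str_hash(s, f.s1);
  const uint64_t b = str_hash(s, f.s2) | 1ULL;  // odd stride
  pos.resize(f.h);
  for (int i = 0; i < f.h; ++i)
    pos[i] = (a + (uint64_t)i * b) % f.m;
}

// decode one canonical key: 0 when any membership bit is unset, else the
// integer assembled from the h count-plane bits (bit i least significant
// first). Membership bits are never cleared, so a passing key was either
// inserted (true count >= 1) or is a false positive; an assembled 0 is
// therefore always a collision artifact and is clamped to 1, keeping
// "decoded > 0" exact for every inserted key.
static inline int decode_key(const std::string &s, const CbfView &f,
                             std::vector<uint64_t> &scratch) {
  key_positions(s, f, scratch);
  for (int i = 0; i < f.h; ++i)
    if (!get_bit(f.bp, scratch[i])) return 0;
  int val = 0;
  for (int i = 0; i < f.h; ++i)
    val |= get_bit(f.bm, scratch[i]) << i;
  return val ? val : 1;
}

// Insert counted k-mers. Membership bits are set; count bits are *assigned*
// (last write wins), so colliding keys may corrupt each other's counts.
// Returns fresh copies of the planes (the inputs are not modified).
// [[Rcpp::export]]
List rc_cbf_insert(RawVector b_plus, RawVector b_minus,
                   CharacterVector kmers, IntegerVector counts,
                   double m, int h, int seed1, int seed2) {
  RawVector bp = clone(b_plus);
  RawVector bm = clone(b_minus);
  unsigned char *p = (unsigned char *)RAW(bp);
  unsigned char *q = (unsigned char *)RAW(bm);
  const uint64_t M = (uint64_t)m;
  const uint64_t s1 = splitmix64((uint64_t)(uint32_t)seed1);
  const uint64_t s2 = splitmix64((uint64_t)(uint32_t)seed2 + 0x6A09E667F3BCC909ULL);
  const int cap = (h >= 31) ? INT_MAX : ((1 << h) - 1);
  std::string cn;
  std::vector<uint64_t> pos;
  CbfView view{p, q, M, h, s1, s2};
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    const std::string s = as<std::string>(kmers[j]);
    if (!canon_str(s, cn))
      stop("non-ACGT character in k-mer %d: '%s'", (int)(j + 1), s.c_str());
    int f = counts[j];
    if (f < 0) stop("negative count at k-mer %d", (int)(j + 1));
    if (f > cap) f = cap;  // saturate at 2^h - 1
    key_positions(cn, view, pos);
    for (int i = 0; i < h; ++i) {
      set_bit(p, pos[i], 1);
      set_bit(q, pos[i], (f >> i) & 1);
    }
  }
  return List::create(_["b_plus"] = bp, _["b_minus"] = bm);
}

// [[Rcpp::export]]
IntegerVector rc_cbf_decode(RawVector b_plus, RawVector b_minus,
                            CharacterVector queries,
                            double m, int h, int seed1, int seed2) {
  const CbfView view{(const unsigned char *)RAW(b_plus),
                     (const unsigned char *)RAW(b_minus),
                     (uint64_t)m, h,
                     splitmix64((uint64_t)(uint32_t)seed1),
                     splitmix64((uint64_t)(uint32_t)seed2 + 0x6A09E667F3BCC909ULL)};
  const R_xlen_t n = queries.size();
  IntegerVector out(n);
  std::string cn;
  std::vector<uint64_t> scratch;
  for (R_xlen_t j = 0; j < n; ++j) {
    const std::string s = as<std::string>(queries[j]);
    if (!canon_str(s, cn))
      stop("non-ACGT character in query %d: '%s'", (int)(j + 1), s.c_str());
    out[j] = decode_key(cn, view, scratch);
  }
  return out;
}

// z-score of each k-mer against its present Hamming-distance-1 neighbors.
// N'_kappa = {kappa} + distinct canonical substitution neighbors with a
// positive decoded count; z = (f - mean)/sd with the population sd.
// [[Rcpp::export]]
List rc_zscore(CharacterVector kmers, IntegerVector counts,
               RawVector b_plus, RawVector b_minus,
               double m, int h, int seed1, int seed2) {
  const CbfView view{(const unsigned char *)RAW(b_plus),
                     (const unsigned char *)RAW(b_minus),
                     (uint64_t)m, h,
                     splitmix64((uint64_t)(uint32_t)seed1),
                     splitmix64((uint64_t)(uint32_t)seed2 + 0x6A09E667F3BCC909ULL)};
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const R_xlen_t n = kmers.size();
  NumericVector z(n), sigma(n);
  IntegerVector n_neighbors(n);
  std::string nb, cn, self;
  std::vector<uint64_t> scratch;
  std::vector<uint64_t> seen;  // primary hashes of canonical neighbors
  for (R_xlen_t j = 0; j < n; ++j) {
    const std::string s = as<std::string>(kmers[j]);
    if (!canon_str(s, self))
      stop("non-ACGT character in k-mer %d: '%s'", (int)(j + 1), s.c_str());
    const double f = (double)counts[j];
    seen.clear();
    double sum = f, sumsq = f * f;
    int cnt = 1;  // kappa itself
    // two substitution neighbors can share a canonical form (or fold onto
    // kappa itself) only when kappa is within Hamming distance 2 of its
    // own reverse complement; skip the dedup bookkeeping otherwise
    std::string self_rc;
    revcomp_str(self, self_rc);
    int rc_dist = 0;
    for (size_t q = 0; q < self.size() && rc_dist <= 2; ++q)
      rc_dist += (self[q] != self_rc[q]);
    const bool need_dedup = (rc_dist <= 2);
    nb = self;
    for (size_t pos = 0; pos < self.size(); ++pos) {
      const char orig = self[pos];
      for (int b = 0; b < 4; ++b) {
        if (BASES[b] == orig) continue;
        nb[pos] = BASES[b];
        canon_str(nb, cn);
        if (need_dedup) {
          if (cn == self) continue;        // revcomp folding onto kappa
          const uint64_t hh = str_hash(cn, view.s1);
          bool dup = false;
          for (size_t q = 0; q < seen.size() && !dup; ++q)
            dup = (seen[q] == hh);
          if (dup) continue;
          seen.push_back(hh);
        }
        const int v = decode_key(cn, view, scratch);
        if (v > 0) {
          sum += v;
          sumsq += (double)v * v;
          ++cnt;
        }
      }
      nb[pos] = orig;
    }
    const double mu = sum / cnt;
    double var = sumsq / cnt - mu * mu;
    if (var < 0) var = 0;
    const double sd = std::sqrt(var);
    sigma[j] = sd;
    n_neighbors[j] = cnt - 1;
    z[j] = (sd > 0) ? (f - mu) / sd : 0.0;
  }
  return List::create(_["z"] = z, _["sigma"] = sigma,
                      _["n_neighbors"] = n_neighbors);
}

// Bidirectional seed extension along unambiguous (k-1)-overlaps in the
// child store: right phase then left phase, each stopping independently on
// branch (>1 continuations), dead end (0) or the overall length cap.
// [[Rcpp::export]]
List rc_extend(std::string seed, RawVector b_plus, RawVector b_minus,
               double m, int h, int seed1, int seed2, int max_len) {
  const CbfView view{(const unsigned char *)RAW(b_plus),
                     (const unsigned char *)RAW(b_minus),
                     (uint64_t)m, h,
                     splitmix64((uint64_t)(uint32_t)seed1),
                     splitmix64((uint64_t)(uint32_t)seed2 + 0x6A09E667F3BCC909ULL)};
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int k = (int)seed.size();
  if (max_len < k) stop("max_len must be >= k");
  std::string s = seed, cand(k, 'A'), cn;
  std::vector<uint64_t> scratch;
  std::string right_stop, left_stop;

  // right phase: suffix(s, k-1) + x
  for (;;) {
    int c = 0;
    char e = 0;
    cand.assign(s, s.size() - (k - 1), k - 1);
    cand.push_back('A');
    for (int b = 0; b < 4; ++b) {
      cand[k - 1] = BASES[b];
      canon_str(cand, cn);
      if (decode_key(cn, view, scratch) > 0) { ++c; e = BASES[b]; }
    }
    if (c == 0)      { right_stop = "dead_end"; break; }
    else if (c > 1)  { right_stop = "branch";   break; }
    if ((int)s.size() + 1 > max_len) { right_stop = "max_len"; break; }
    s.push_back(e);
  }

  // left phase: x + prefix(s, k-1)
  for (;;) {
    int c = 0;
    char e = 0;
    cand.assign(1, 'A');
    cand.append(s, 0, k - 1);
    for (int b = 0; b < 4; ++b) {
      cand[0] = BASES[b];
      canon_str(cand, cn);
      if (decode_key(cn, view, scratch) > 0) { ++c; e = BASES[b]; }
    }
    if (c == 0)      { left_stop = "dead_end"; break; }
    else if (c > 1)  { left_stop = "branch";   break; }
    if ((int)s.size() + 1 > max_len) { left_stop = "max_len"; break; }
    s.insert(s.begin(), e);
  }

  return List::create(_["sequence"] = s,
                      _["left_stop"] = left_stop,
                      _["right_stop"] = right_stop);
}

// Containment filter for contigs: drop a sequence when it (or its reverse
// complement) is a substring of an earlier kept sequence. Callers pass
// sequences sorted longest-first for a deterministic result.
// [[Rcpp::export]]
LogicalVector rc_dedup_contained(CharacterVector seqs) {
  const R_xlen_t n = seqs.size();
  LogicalVector keep(n);
  std::vector<std::string> kept;
  kept.reserve(n);
  std::string rc;
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    if (!revcomp_str(s, rc))
      stop("non-ACGT character in contig %d", (int)(i + 1));
    bool contained = false;
    for (size_t j = 0; j < kept.size() && !contained; ++j) {
      if (kept[j].size() < s.size()) continue;
      if (kept[j].find(s) != std::string::npos ||
          kept[j].find(rc) != std::string::npos)
        contained = true;
    }
    keep[i] = !contained;
    if (!contained) kept.push_back(s);
  }
  return keep;
}
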