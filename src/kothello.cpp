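// Core primitives: 2-bit k-mer packing, seeded hashing, acyclic-XOR Othello
// construction/query, l-bit array packing, and bulk k-mer generators.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_set>
#include <random>
using namespace Rcpp;

// ---- k-mer packing ---------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Pack a k-mer into a 64-bit integer, first base in the most significant
// 2-bit slot. Returns false on any non-ACGT character.
static bool pack_kmer(const char* s, int k, uint64_t& out) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    x = (x << 2) | (uint64_t)c;
  }
  out = x;
  return true;
}

static inline uint64_t revcomp_packed(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static inline uint64_t canonical_packed(uint64_t x, int k) {
  uint64_t r = revcomp_packed(x, k);
  return x < r ? x : r;
}

static std::string unpack_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// ---- hashing ---------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// One 64-bit hash per key, split into the two array indices; m_a and m_b are
// powers of two so masking suffices.
static inline void hash_pair(uint64_t key, uint32_t seed,
                             uint64_t ma, uint64_t mb,
                             uint64_t& ha, uint64_t& hb) {
  uint64_t h = splitmix64(key ^ ((uint64_t)seed * 0xD6E8FEB86659FD93ULL));
  ha = h & (ma - 1);
  hb = (h >> 32) & (mb - 1);
}

static std::vector<uint64_t> pack_keys(const CharacterVector& keys,
                                       bool canonical) {
  R_xlen_t n = keys.size();
  if (n == 0) stop("empty key set");
  int k = LENGTH(STRING_ELT(keys, 0));
  std::vector<uint64_t> packed(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(keys, i);
    if (el == NA_STRING || LENGTH(el) != k)
      stop("key %d is not a %d-mer", (int)(i + 1), k);
    uint64_t x;
    if (!pack_kmer(CHAR(el), k, x))
      stop("key '%s' contains a non-ACGT character", CHAR(el));
    packed[i] = canonical ? canonical_packed(x, k) : x;
  }
  return packed;
}

// ---- Othello construction --------------------------------------------------

// Keys are edges of a bipartite graph on m_a + m_b nodes. If the multigraph
// is acyclic (degree-1 peeling removes every edge), values are assigned in
// reverse peel order so A[h_a] XOR B[h_b] = value along every edge;
// untouched entries stay 0. On a cycle, the seed is advanced and the build
// retried.
// [[Rcpp::export]]
List cpp_othello_build(CharacterVector keys, IntegerVector values,
                       int ma, int mb, int base_seed, int max_retries) {
  R_xlen_t n = keys.size();
  if (values.size() != n) stop("keys and values differ in length");
  std::vector<uint64_t> packed = pack_keys(keys, false);

  {
    std::unordered_set<uint64_t> seen;
    seen.reserve(n * 2);
    for (R_xlen_t i = 0; i < n; ++i)
      if (!seen.insert(packed[i]).second)
        stop("duplicate key '%s'", CHAR(STRING_ELT(keys, i)));
  }

  size_t N = (size_t)ma + (size_t)mb;
  std::vector<int> head(N), ptr(N), deg(N);
  std::vector<int> nxt(2 * (size_t)n), eto(2 * (size_t)n);
  std::vector<uint64_t> ea(n), eb(n);
  std::vector<char> dead(n);
  std::vector<int> peel_edge(n), peel_node(n);
  std::vector<int> stack;
  stack.reserve(N);

  for (int attempt = 0; attempt < max_retries; ++attempt) {
    uint32_t seed = (uint32_t)base_seed + (uint32_t)attempt;
    std::fill(head.begin(), head.end(), -1);
    std::fill(deg.begin(), deg.end(), 0);
    std::fill(dead.begin(), dead.end(), 0);

    for (R_xlen_t e = 0; e < n; ++e) {
      uint64_t ha, hb;
      hash_pair(packed[e], seed, (uint64_t)ma, (uint64_t)mb, ha, hb);
      ea[e] = ha;
      eb[e] = (uint64_t)ma + hb;
      // two half-edges per edge: 2e at node ea, 2e+1 at node eb
      size_t u = ha, w = (size_t)ma + hb;
      nxt[2 * e] = head[u]; head[u] = 2 * (int)e; eto[2 * e] = (int)w;
      nxt[2 * e + 1] = head[w]; head[w] = 2 * (int)e + 1; eto[2 * e + 1] = (int)u;
      deg[u]++; deg[w]++;
    }
    ptr = head;

    stack.clear();
    for (size_t u = 0; u < N; ++u)
      if (deg[u] == 1) stack.push_back((int)u);

    R_xlen_t peeled = 0;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      if (deg[u] != 1) continue;
      // advance past dead half-edges (they never revive)
      int he = ptr[u];
      while (he >= 0 && dead[he >> 1]) he = nxt[he];
      ptr[u] = he;
      if (he < 0) continue;
      int e = he >> 1;
      int w = eto[he];
      dead[e] = 1;
      deg[u] = 0;
      deg[w]--;
      peel_edge[peeled] = e;
      peel_node[peeled] = u;
      ++peeled;
      if (deg[w] == 1) stack.push_back(w);
    }

    if (peeled == n) {
      IntegerVector A(ma), B(mb);
      for (R_xlen_t i = n - 1; i >= 0; --i) {
        int e = peel_edge[i];
        int u = peel_node[i];
        int other = ((size_t)u == ea[e]) ? (int)eb[e] : (int)ea[e];
        int oval = other < ma ? A[other] : B[other - ma];
        int forced = values[e] ^ oval;
        if (u < ma) A[u] = forced; else B[u - ma] = forced;
      }
      return List::create(_["A"] = A, _["B"] = B,
                          _["seed"] = (int)seed,
                          _["attempts"] = attempt + 1);
    }
  }
  stop("Othello construction failed after %d hash reseeds", max_retries);
}

// [[Rcpp::export]]
IntegerVector cpp_othello_query(CharacterVector keys, IntegerVector A,
                                IntegerVector B, int seed) {
  std::vector<uint64_t> packed = pack_keys(keys, false);
  uint64_t ma = A.size(), mb = B.size();
  R_xlen_t n = packed.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t ha, hb;
    hash_pair(packed[i], (uint32_t)seed, ma, mb, ha, hb);
    out[i] = A[ha] ^ B[hb];
  }
  return out;
}

// ---- k-mer utilities -------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector kmers, int k) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(kmers, i);
    uint64_t x;
    if (el == NA_STRING || LENGTH(el) != k || !pack_kmer(CHAR(el), k, x)) {
      out[i] = NA_STRING;
      continue;
    }
    out[i] = unpack_kmer(canonical_packed(x, k), k);
  }
  return out;
}

// Sliding-window decomposition; windows touching a non-ACGT base are NA.
// [[Rcpp::export]]
CharacterVector cpp_decompose(std::string seq, int k, bool canonical) {
  int L = (int)seq.size();
  if (L < k) return CharacterVector(0);
  int n = L - k + 1;
  std::vector<int> code(L);
  for (int i = 0; i < L; ++i) code[i] = base_code(seq[i]);
  CharacterVector out(n);
  int last_bad = -1;
  uint64_t x = 0;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < L; ++i) {
    if (code[i] < 0) { last_bad = i; x = (x << 2) & mask; }
    else x = ((x << 2) | (uint64_t)code[i]) & mask;
    int start = i - k + 1;
    if (start < 0) continue;
    if (last_bad >= start) out[start] = NA_STRING;
    else out[start] = unpack_kmer(canonical ? canonical_packed(x, k) : x, k);
  }
  return out;
}

// All valid k-mers of a set of sequences, concatenated (not deduplicated).
// [[Rcpp::export]]
CharacterVector cpp_kmers_of_seqs(CharacterVector seqs, int k, bool canonical) {
  std::vector<std::string> acc;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int L = (int)seq.size();
    if (L < k) continue;
    int last_bad = -1;
    uint64_t x = 0;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int i = 0; i < L; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { last_bad = i; x = (x << 2) & mask; }
      else x = ((x << 2) | (uint64_t)c) & mask;
      int start = i - k + 1;
      if (start < 0 || last_bad >= start) continue;
      acc.push_back(unpack_kmer(canonical ? canonical_packed(x, k) : x, k));
    }
  }
  return wrap(acc);
}

// n k-mers drawn uniformly from the 4^k universe (mt19937_64, own stream so
// results do not depend on R's RNG state).
// [[Rcpp::export]]
CharacterVector cpp_random_kmers(int n, int k, int seed, bool canonical,
                                 bool distinct) {
  std::mt19937_64 rng((uint64_t)(uint32_t)seed);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  CharacterVector out(n);
  std::unordered_set<uint64_t> seen;
  if (distinct) seen.reserve(2 * (size_t)n);
  int got = 0;
  while (got < n) {
    uint64_t x = rng() & mask;
    if (canonical) x = canonical_packed(x, k);
    if (distinct && !seen.insert(x).second) continue;
    out[got++] = unpack_kmer(x, k);
  }
  return out;
}

// n uniform k-mers avoiding an exclusion set (alien probes).
// [[Rcpp::export]]
CharacterVector cpp_alien_kmers(int n, int k, int seed,
                                CharacterVector exclude, bool canonical,
                                bool distinct) {
  std::unordered_set<uint64_t> excl;
  excl.reserve(2 * (size_t)exclude.size() + 1);
  for (R_xlen_t i = 0; i < exclude.size(); ++i) {
    SEXP el = STRING_ELT(exclude, i);
    uint64_t x;
    if (el == NA_STRING || LENGTH(el) != k || !pack_kmer(CHAR(el), k, x))
      stop("exclusion entry %d is not a valid %d-mer", (int)(i + 1), k);
    excl.insert(canonical ? canonical_packed(x, k) : x);
  }
  std::mt19937_64 rng((uint64_t)(uint32_t)seed);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  CharacterVector out(n);
  std::unordered_set<uint64_t> seen;
  if (distinct) seen.reserve(2 * (size_t)n);
  int got = 0;
  while (got < n) {
    uint64_t x = rng() & mask;
    if (canonical) x = canonical_packed(x, k);
    if (excl.count(x)) continue;
    if (distinct && !seen.insert(x).second) continue;
    out[got++] = unpack_kmer(x, k);
  }
  return out;
}

// ---- l-bit little-endian packing ------------------------------------------

// [[Rcpp::export]]
RawVector cpp_pack_lbits(IntegerVector vals, int l) {
  size_t nbits = (size_t)vals.size() * (size_t)l;
  RawVector out((nbits + 7) / 8);
  std::fill(out.begin(), out.end(), 0);
  size_t pos = 0;
  for (R_xlen_t i = 0; i < vals.size(); ++i) {
    uint32_t v = (uint32_t)vals[i];
    for (int j = 0; j < l; ++j, ++pos)
      if ((v >> j) & 1u) out[pos >> 3] |= (Rbyte)(1u << (pos & 7));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack_lbits(RawVector bytes, int l, int n) {
  if ((size_t)bytes.size() * 8 < (size_t)n * (size_t)l)
    stop("byte stream too short for %d %d-bit values", n, l);
  IntegerVector out(n);
  size_t pos = 0;
  for (int i = 0; i < n; ++i) {
    uint32_t v = 0;
    for (int j = 0; j < l; ++j, ++pos)
      if ((bytes[pos >> 3] >> (pos & 7)) & 1u) v |= (1u << j);
    out[i] = (int)v;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_fnv1a32(RawVector bytes) {
  uint32_t h = 2166136261u;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint32_t)bytes[i];
    h *= 16777619u;
  }
  return (double)h;
}
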