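#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// MurmurHash3 x64 128-bit, lower 64 bits kept. Standard public-domain
// construction; seeded so sketches are reproducible by parameter alone.
static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static uint64_t murmur3_x64_64(const char *key, int len, uint32_t seed) {
  const uint8_t *data = (const uint8_t *)key;
  const int nblocks = len / 16;
  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  const uint64_t *blocks = (const uint64_t *)(data);
  for (int i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, blocks + i * 2, 8);
    std::memcpy(&k2, blocks + i * 2 + 1, 8);
    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t *tail = (const uint8_t *)(data + nblocks * 16);
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
  case 15: k2 ^= ((uint64_t)tail[14]) << 48; /* fallthrough */
  case 14: k2 ^= ((uint64_t)tail[13]) << 40; /* fallthrough */
  case 13: k2 ^= ((uint64_t)tail[12]) << 32; /* fallthrough */
  case 12: k2 ^= ((uint64_t)tail[11]) << 24; /* fallthrough */
  case 11: k2 ^= ((uint64_t)tail[10]) << 16; /* fallthrough */
  case 10: k2 ^= ((uint64_t)tail[9]) << 8;   /* fallthrough */
  case 9:  k2 ^= ((uint64_t)tail[8]);
           k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2; /* fallthrough */
  case 8:  k1 ^= ((uint64_t)tail[7]) << 56; /* fallthrough */
  case 7:  k1 ^= ((uint64_t)tail[6]) << 48; /* fallthrough */
  case 6:  k1 ^= ((uint64_t)tail[5]) << 40; /* fallthrough */
  case 5:  k1 ^= ((uint64_t)tail[4]) << 32; /* fallthrough */
  case 4:  k1 ^= ((uint64_t)tail[3]) << 24; /* fallthrough */
  case 3:  k1 ^= ((uint64_t)tail[2]) << 16; /* fallthrough */
  case 2:  k1 ^= ((uint64_t)tail[1]) << 8;  /* fallthrough */
  case 1:  k1 ^= ((uint64_t)tail[0]);
           k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= len; h2 ^= len;
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2;
  return h1;
}

// Hash values are masked to 53 bits so every value is exactly representable
// as an R double; ordering and uniformity are unaffected at sketch scales.
static const uint64_t MASK53 = (1ULL << 53) - 1;

static inline char upcase(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 0;
  }
}

// Bottom-s sketch of canonical k-mer hashes across all scaffolds.
// Windows containing non-ACGT letters are skipped.
// [[Rcpp::export]]
NumericVector cpp_sketch_hashes(CharacterVector scaffolds, int k, int s,
                                int seed) {
  if (k < 1) stop("k must be >= 1");
  if (s < 1) stop("sketch size must be >= 1");
  std::set<uint64_t> bottom;  // ordered; largest element cheap to find
  std::string kmer(k, 'N'), rc(k, 'N');
  for (int sc = 0; sc < scaffolds.size(); sc++) {
    const char *seq = CHAR(STRING_ELT(scaffolds, sc));
    int len = (int)std::strlen(seq);
    if (len < k) continue;
    int valid = 0;  // length of current run of ACGT letters ending at i
    for (int i = 0; i < len; i++) {
      char c = upcase(seq[i]);
      if (complement(c) == 0) { valid = 0; continue; }
      valid++;
      if (valid < k) continue;
      const char *start = seq + i - k + 1;
      for (int j = 0; j < k; j++) {
        kmer[j] = upcase(start[j]);
        rc[k - 1 - j] = complement(kmer[j]);
      }
      const std::string &canon = (rc < kmer) ? rc : kmer;
      uint64_t h = murmur3_x64_64(canon.data(), k, (uint32_t)seed) & MASK53;
      if ((int)bottom.size() < s) {
        bottom.insert(h);
      } else if (h < *bottom.rbegin()) {
        if (bottom.insert(h).second) bottom.erase(std::prev(bottom.end()));
      }
    }
  }
  NumericVector out(bottom.size());
  int i = 0;
  for (std::set<uint64_t>::const_iterator it = bottom.begin();
       it != bottom.end(); ++it)
    out[i++] = (double)*it;
  return out;
}

// Exact canonical k-mer set hashes (no bottom-s truncation); used for the
// dense hexamer-profile path and for small-genome exact Jaccard.
// [[Rcpp::export]]
NumericVector cpp_all_kmer_hashes(CharacterVector scaffolds, int k, int seed) {
  std::set<uint64_t> all;
  std::string kmer(k, 'N'), rc(k, 'N');
  for (int sc = 0; sc < scaffolds.size(); sc++) {
    const char *seq = CHAR(STRING_ELT(scaffolds, sc));
    int len = (int)std::strlen(seq);
    if (len < k) continue;
    int valid = 0;
    for (int i = 0; i < len; i++) {
      char c = upcase(seq[i]);
      if (complement(c) == 0) { valid = 0; continue; }
      valid++;
      if (valid < k) continue;
      const char *start = seq + i - k + 1;
      for (int j = 0; j < k; j++) {
        kmer[j] = upcase(start[j]);
        rc[k - 1 - j] = complement(kmer[j]);
      }
      const std::string &canon = (rc < kmer) ? rc : kmer;
      all.insert(murmur3_x64_64(canon.data(), k, (uint32_t)seed) & MASK53);
    }
  }
  NumericVector out(all.size());
  int i = 0;
  for (std::set<uint64_t>::const_iterator it = all.begin(); it != all.end();
       ++it)
    out[i++] = (double)*it;
  return out;
}
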