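#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Reverse complement restricted to A/C/G/T; returns false on any other char.
static inline bool revcomp_inplace(std::string &s) {
  const std::size_t n = s.size();
  std::string out(n, 'N');
  for (std::size_t i = 0; i < n; ++i) {
    char c = s[n - 1 - i];
    switch (c) {
    case 'A': out[i] = 'T'; break;
    case 'C': out[i] = 'G'; break;
    case 'G': out[i] = 'C'; break;
    case 'T': out[i] = 'A'; break;
    default: return false;
    }
  }
  s.swap(out);
  return true;
}

// [[Rcpp::export(name = ".extract_kmers_cpp")]]
CharacterVector extract_kmers_cpp(std::string seq, int k, bool canonical) {
  std::unordered_set<std::string> seen;
  std::vector<std::string> out;
  const std::size_t n = seq.size();
  if (k < 1 || (std::size_t)k > n) return CharacterVector(0);
  // windows overlapping a non-ACGT base are skipped entirely; track the
  // most recent invalid position while sliding
  std::ptrdiff_t last_bad = -1;
  for (std::size_t j = 0; j + 1 < (std::size_t)k; ++j) {
    char c = seq[j];
    if (!(c == 'A' || c == 'C' || c == 'G' || c == 'T')) last_bad = j;
  }
  for (std::size_t i = 0; i + k <= n; ++i) {
    char c = seq[i + k - 1];
    if (!(c == 'A' || c == 'C' || c == 'G' || c == 'T')) last_bad = i + k - 1;
    if (last_bad >= (std::ptrdiff_t)i) continue;
    std::string w = seq.substr(i, k);
    if (canonical) {
      std::string rc = w;
      revcomp_inplace(rc);
      if (rc < w) w.swap(rc);
    }
    if (seen.insert(w).second) out.push_back(w);
  }
  return wrap(out);
}

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Seeded 64-bit FNV-1a with a splitmix64 finalizer, mapped to [0, 1).
// Mapping to double keeps ordering; the 53-bit mantissa makes ties
// vanishingly rare at sketch scale.
// [[Rcpp::export(name = ".hash_kmers_cpp")]]
NumericVector hash_kmers_cpp(CharacterVector kmers, double seed) {
  const std::uint64_t fnv_offset = 0xCBF29CE484222325ULL;
  const std::uint64_t fnv_prime = 0x100000001B3ULL;
  const std::uint64_t seed64 = splitmix64((std::uint64_t)seed);
  const R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    std::uint64_t h = fnv_offset ^ seed64;
    for (const char *p = s; *p; ++p) {
      h ^= (std::uint64_t)(unsigned char)(*p);
      h *= fnv_prime;
    }
    h = splitmix64(h);
    out[i] = (double)(h >> 11) / 9007199254740992.0; // 2^53
  }
  return out;
}
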