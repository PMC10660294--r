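#pragma once

#include <cstdint>
#include <string>
#include <array>
#include <stdexcept>

namespace pephash {

// canonical residue order: the 20 standard amino acids, alphabetical
constexpr const char* ALPHABET = "ACDEFGHIKLMNPQRSTVWY";
constexpr int NAA = 20;

inline const std::array<int, 256>& aa_index_table() {
  static std::array<int, 256> tab = [] {
    std::array<int, 256> t{};
    t.fill(-1);
    for (int i = 0; i < NAA; ++i) {
      unsigned char up = static_cast<unsigned char>(ALPHABET[i]);
      t[up] = i;
      t[up + 32] = i;  // lowercase: FASTA case is not semantic
    }
    return t;
  }();
  return tab;
}

inline int aa_index(char c) {
  return aa_index_table()[static_cast<unsigned char>(c)];
}

// Split-register rotation: bits 0..32 (33-bit register) and bits 33..63
// (31-bit register) each rotate left by one, independently.  Period is
// lcm(33, 31) = 1023 instead of 64 for a plain rotation.
constexpr uint64_t LO_MASK = 0x1FFFFFFFFULL;  // 33 ones
constexpr uint64_t HI_MASK = 0x7FFFFFFFULL;   // 31 ones

inline uint64_t srol1(uint64_t x) {
  uint64_t lo = x & LO_MASK;
  uint64_t hi = x >> 33;
  lo = ((lo << 1) | (lo >> 32)) & LO_MASK;
  hi = ((hi << 1) | (hi >> 30)) & HI_MASK;
  return (hi << 33) | lo;
}

inline uint64_t srol_n(uint64_t x, uint64_t n) {
  unsigned rl = static_cast<unsigned>(n % 33);
  unsigned rh = static_cast<unsigned>(n % 31);
  uint64_t lo = x & LO_MASK;
  uint64_t hi = x >> 33;
  if (rl) lo = ((lo << rl) | (lo >> (33 - rl))) & LO_MASK;
  if (rh) hi = ((hi << rh) | (hi >> (31 - rh))) & HI_MASK;
  return (hi << 33) | lo;
}

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

// splitmix64: seed-table generation and test RNG (public-domain mixer,
// re-implemented)
inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// hash index i (i >= 1) derived from the canonical hash: odd multiplier from
// (i, k), then a two-round xorshift-multiply finalizer.  Bijective in `base`
// for fixed (i, k), so uniform bases give uniform derived hashes.
inline uint64_t multi_hash_i(uint64_t base, uint64_t i, uint64_t k) {
  uint64_t mult = ((i * 0x9E3779B97F4A7C15ULL) ^ (k * 0xC2B2AE3D27D4EB4FULL)) | 1ULL;
  uint64_t z = base * mult;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline std::string u64_to_hex(uint64_t x) {
  static const char* digits = "0123456789abcdef";
  std::string s(16, '0');
  for (int i = 15; i >= 0; --i) {
    s[i] = digits[x & 0xF];
    x >>= 4;
  }
  return s;
}

inline uint64_t hex_to_u64(const std::string& s) {
  if (s.size() != 16)
    throw std::invalid_argument("hash words must be 16 hex digits, got '" + s + "'");
  uint64_t x = 0;
  for (char c : s) {
    int v;
    if (c >= '0' && c <= '9') v = c - '0';
    else if (c >= 'a' && c <= 'f') v = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') v = c - 'A' + 10;
    else throw std::invalid_argument(std::string("invalid hex digit '") + c + "'");
    x = (x << 4) | static_cast<uint64_t>(v);
  }
  return x;
}

// 2^64 - 1 as double (normalization denominator)
constexpr double U64_MAX_D = 18446744073709551615.0;

}  // namespace pephash
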