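#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include "hash64.h"

using namespace Rcpp;
using namespace pephash;

static std::array<uint64_t, NAA> parse_seed_table(const CharacterVector& seeds) {
  if (seeds.size() != NAA)
    stop("seed table must have exactly %d entries, got %d", NAA, (int)seeds.size());
  std::array<uint64_t, NAA> tab;
  for (int i = 0; i < NAA; ++i) tab[i] = hex_to_u64(as<std::string>(seeds[i]));
  return tab;
}

// [[Rcpp::export]]
CharacterVector cpp_generate_base_seeds(int rng_seed, int pop_lo = 30, int pop_hi = 34) {
  uint64_t state = static_cast<uint64_t>(static_cast<int64_t>(rng_seed));
  std::vector<uint64_t> out;
  out.reserve(NAA);
  int guard = 0;
  while ((int)out.size() < NAA) {
    if (++guard > 100000) stop("seed generation did not converge");
    uint64_t w = splitmix64(state);
    int pc = popcount64(w);
    if (pc < pop_lo || pc > pop_hi) continue;
    bool dup = false;
    for (uint64_t prev : out) if (prev == w) { dup = true; break; }
    if (!dup) out.push_back(w);
  }
  CharacterVector res(NAA);
  for (int i = 0; i < NAA; ++i) res[i] = u64_to_hex(out[i]);
  return res;
}

// [[Rcpp::export]]
CharacterVector cpp_srol(CharacterVector x, double n = 1) {
  if (n < 0) stop("rotation count must be nonnegative");
  uint64_t nn = static_cast<uint64_t>(n);
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = u64_to_hex(srol_n(hex_to_u64(as<std::string>(x[i])), nn));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_xor64(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if ((a.size() != n && a.size() != 1) || (b.size() != n && b.size() != 1))
    stop("arguments must have equal length (or length 1)");
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t x = hex_to_u64(as<std::string>(a[a.size() == 1 ? 0 : i]));
    uint64_t y = hex_to_u64(as<std::string>(b[b.size() == 1 ? 0 : i]));
    out[i] = u64_to_hex(x ^ y);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_popcount(CharacterVector x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = popcount64(hex_to_u64(as<std::string>(x[i])));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hex_to_norm(CharacterVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = static_cast<double>(hex_to_u64(as<std::string>(x[i]))) / U64_MAX_D;
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_random_hex(int n, int rng_seed) {
  uint64_t state = static_cast<uint64_t>(static_cast<int64_t>(rng_seed));
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = u64_to_hex(splitmix64(state));
  return out;
}

// dimer[a*20+b]  = srol(seed a) ^ seed b
// trimer[(a*20+b)*20+c] = srol(dimer(a,b)) ^ seed c
struct NmerTab {
  std::vector<uint64_t> dimer, trimer;
};

static NmerTab build_nmer(const std::array<uint64_t, NAA>& seeds) {
  NmerTab t;
  t.dimer.resize(NAA * NAA);
  t.trimer.resize(NAA * NAA * NAA);
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b)
      t.dimer[a * NAA + b] = srol1(seeds[a]) ^ seeds[b];
  for (int a = 0; a < NAA; ++a)
    for (int b = 0; b < NAA; ++b)
      for (int c = 0; c < NAA; ++c)
        t.trimer[(a * NAA + b) * NAA + c] = srol1(t.dimer[a * NAA + b]) ^ seeds[c];
  return t;
}

// [[Rcpp::export]]
List cpp_build_nmer_tables(CharacterVector seeds) {
  auto tab = parse_seed_table(seeds);
  NmerTab t = build_nmer(tab);
  CharacterVector dim(t.dimer.size()), tri(t.trimer.size());
  for (size_t i = 0; i < t.dimer.size(); ++i) dim[i] = u64_to_hex(t.dimer[i]);
  for (size_t i = 0; i < t.trimer.size(); ++i) tri[i] = u64_to_hex(t.trimer[i]);
  return List::create(_["dimer"] = dim, _["trimer"] = tri);
}

// Base hash of one window, chunked through the trimer/dimer tables; by
// linearity of srol over XOR this is bit-identical to the per-residue scan.
static uint64_t hash_base_tab(const char* s, int k,
                              const std::array<uint64_t, NAA>& seeds,
                              const NmerTab& nm) {
  uint64_t H = 0;
  int pos = 0, rem = k;
  while (rem >= 3) {
    int a = aa_index(s[pos]), b = aa_index(s[pos + 1]), c = aa_index(s[pos + 2]);
    H = srol_n(H, 3) ^ nm.trimer[(a * NAA + b) * NAA + c];
    pos += 3; rem -= 3;
  }
  if (rem >= 2) {
    int a = aa_index(s[pos]), b = aa_index(s[pos + 1]);
    H = srol_n(H, 2) ^ nm.dimer[a * NAA + b];
    pos += 2; rem -= 2;
  }
  if (rem == 1) H = srol1(H) ^ seeds[aa_index(s[pos])];
  return H;
}

// [[Rcpp::export]]
CharacterVector cpp_hash_kmers(CharacterVector kmers, CharacterVector seeds) {
  auto tab = parse_seed_table(seeds);
  NmerTab nm = build_nmer(tab);
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if (s.empty()) stop("k-mer must have length >= 1");
    for (size_t j = 0; j < s.size(); ++j)
      if (aa_index(s[j]) < 0)
        stop("invalid residue '%c' at offset %d (0-based) in k-mer %d",
             s[j], (int)j, (int)(i + 1));
    out[i] = u64_to_hex(hash_base_tab(s.c_str(), (int)s.size(), tab, nm));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_roll(CharacterVector prev, std::string outgoing,
                         std::string incoming, int k, CharacterVector seeds) {
  if (outgoing.size() != 1 || incoming.size() != 1)
    stop("outgoing/incoming must be single residues");
  int io = aa_index(outgoing[0]), ii = aa_index(incoming[0]);
  if (io < 0) stop("invalid residue '%c' (outgoing)", outgoing[0]);
  if (ii < 0) stop("invalid residue '%c' (incoming)", incoming[0]);
  auto tab = parse_seed_table(seeds);
  CharacterVector out(prev.size());
  for (R_xlen_t i = 0; i < prev.size(); ++i) {
    uint64_t H = hex_to_u64(as<std::string>(prev[i]));
    out[i] = u64_to_hex(srol1(H) ^ srol_n(tab[io], (uint64_t)k) ^ tab[ii]);
  }
  return out;
}

// [[Rcpp::export]]
CharacterMatrix cpp_multi_hash(CharacterVector base, int h, int k) {
  if (h < 1) stop("number of hashes h must be >= 1");
  CharacterMatrix out(base.size(), h);
  for (R_xlen_t i = 0; i < base.size(); ++i) {
    uint64_t b = hex_to_u64(as<std::string>(base[i]));
    out(i, 0) = u64_to_hex(b);
    for (int j = 1; j < h; ++j)
      out(i, j) = u64_to_hex(multi_hash_i(b, (uint64_t)j, (uint64_t)k));
  }
  return out;
}

// Rolling scan with window invalidation: windows containing any non-alphabet
// character are skipped and rolling re-initializes at the next clean window.
template <typename EMIT>
static void scan_rolling(const std::string& seq, int k,
                         const std::array<uint64_t, NAA>& seeds,
                         const NmerTab& nm, EMIT emit) {
  const char* s = seq.c_str();
  R_xlen_t L = (R_xlen_t)seq.size();
  R_xlen_t p = 0;
  bool prev_valid = false;
  uint64_t H = 0;
  while (p + k <= L) {
    if (!prev_valid) {
      // rightmost invalid residue in the window, if any
      R_xlen_t bad = -1;
      for (R_xlen_t j = p; j < p + k; ++j)
        if (aa_index(s[j]) < 0) bad = j;
      if (bad >= 0) { p = bad + 1; continue; }
      H = hash_base_tab(s + p, k, seeds, nm);
    } else {
      char in = s[p + k - 1];
      int ii = aa_index(in);
      if (ii < 0) { prev_valid = false; p = p + k; continue; }
      int io = aa_index(s[p - 1]);
      H = srol1(H) ^ srol_n(seeds[io], (uint64_t)k) ^ seeds[ii];
    }
    emit(p, H);
    prev_valid = true;
    ++p;
  }
}

static List stream_result(const std::vector<R_xlen_t>& pos,
                          const std::vector<uint64_t>& val,
                          int h, int k, bool want_hex, bool want_norm) {
  R_xlen_t n = (R_xlen_t)pos.size();
  IntegerVector rpos(n);
  for (R_xlen_t i = 0; i < n; ++i) rpos[i] = (int)pos[i];
  List out = List::create(_["pos"] = rpos, _["hex"] = R_NilValue, _["norm"] = R_NilValue);
  if (want_hex) {
    CharacterMatrix hx(n, h);
    for (R_xlen_t i = 0; i < n; ++i) {
      hx(i, 0) = u64_to_hex(val[i]);
      for (int j = 1; j < h; ++j)
        hx(i, j) = u64_to_hex(multi_hash_i(val[i], (uint64_t)j, (uint64_t)k));
    }
    out["hex"] = hx;
  }
  if (want_norm) {
    NumericMatrix nm(n, h);
    for (R_xlen_t i = 0; i < n; ++i) {
      nm(i, 0) = static_cast<double>(val[i]) / U64_MAX_D;
      for (int j = 1; j < h; ++j)
        nm(i, j) = static_cast<double>(multi_hash_i(val[i], (uint64_t)j, (uint64_t)k)) / U64_MAX_D;
    }
    out["norm"] = nm;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_hash_stream(std::string seq, int k, CharacterVector seeds, int h = 1,
                     bool want_hex = true, bool want_norm = false) {
  if (k < 1) stop("k must be >= 1");
  if (h < 1) stop("number of hashes h must be >= 1");
  auto tab = parse_seed_table(seeds);
  NmerTab nm = build_nmer(tab);
  std::vector<R_xlen_t> pos;
  std::vector<uint64_t> val;
  if ((R_xlen_t)seq.size() >= k) {
    pos.reserve(seq.size() - k + 1);
    val.reserve(seq.size() - k + 1);
  }
  scan_rolling(seq, k, tab, nm, [&](R_xlen_t p, uint64_t Hv) {
    pos.push_back(p); val.push_back(Hv);
  });
  return stream_result(pos, val, h, k, want_hex, want_norm);
}

// Multi-level pattern hashing: Eq.-(1)-style direct evaluation per window
// with the per-position level's seed table (mixed tables break the rolling
// cancellation, so no rolling here).
// [[Rcpp::export]]
List cpp_pattern_stream(std::string seq, IntegerVector pattern, List tables,
                        int h = 1, bool want_hex = true, bool want_norm = false) {
  int k = (int)pattern.size();
  if (k < 1) stop("pattern must have length >= 1");
  if (h < 1) stop("number of hashes h must be >= 1");
  if (tables.size() != 3) stop("need seed tables for levels 1..3");
  std::array<std::array<uint64_t, NAA>, 3> tabs;
  for (int l = 0; l < 3; ++l) tabs[l] = parse_seed_table(tables[l]);
  std::vector<int> lev(k);
  for (int j = 0; j < k; ++j) {
    lev[j] = pattern[j];
    if (lev[j] < 1 || lev[j] > 3) stop("pattern levels must be in {1,2,3}");
  }
  const char* s = seq.c_str();
  R_xlen_t L = (R_xlen_t)seq.size();
  std::vector<R_xlen_t> pos;
  std::vector<uint64_t> val;
  R_xlen_t p = 0;
  while (p + k <= L) {
    R_xlen_t bad = -1;
    for (R_xlen_t j = p; j < p + k; ++j)
      if (aa_index(s[j]) < 0) bad = j;
    if (bad >= 0) { p = bad + 1; continue; }
    uint64_t H = 0;
    for (int j = 0; j < k; ++j)
      H ^= srol_n(tabs[lev[j] - 1][aa_index(s[p + j])], (uint64_t)(k - 1 - j));
    pos.push_back(p); val.push_back(H);
    ++p;
  }
  return stream_result(pos, val, h, k, want_hex, want_norm);
}

// Canonical-hash overlap estimate between two k-mer collections (exact up to
// 64-bit hash collisions, ~n^2/2^64).
// [[Rcpp::export]]
NumericVector cpp_kmer_overlap(CharacterVector insert_seqs, CharacterVector query_seqs,
                               int k, CharacterVector seeds) {
  auto tab = parse_seed_table(seeds);
  NmerTab nm = build_nmer(tab);
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t i = 0; i < insert_seqs.size(); ++i) {
    std::string s = as<std::string>(insert_seqs[i]);
    scan_rolling(s, k, tab, nm, [&](R_xlen_t, uint64_t Hv) { seen.insert(Hv); });
  }
  double n_query = 0, n_overlap = 0;
  for (R_xlen_t i = 0; i < query_seqs.size(); ++i) {
    std::string s = as<std::string>(query_seqs[i]);
    scan_rolling(s, k, tab, nm, [&](R_xlen_t, uint64_t Hv) {
      n_query += 1;
      if (seen.count(Hv)) n_overlap += 1;
    });
  }
  return NumericVector::create(n_query, n_overlap);
}
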