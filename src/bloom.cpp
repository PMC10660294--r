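#include <Rcpp.h>
#include <vector>
#include <cstdio>
#include "hash64.h"

using namespace Rcpp;
using namespace pephash;

// m-bit array, h hash functions per element, plain mod-m addressing
struct BloomF {
  uint64_t m, h, n_inserted;
  std::vector<uint64_t> bits;
  BloomF(uint64_t m_, uint64_t h_)
      : m(m_), h(h_), n_inserted(0), bits((m_ + 63) / 64, 0ULL) {}
  void set(uint64_t v) {
    uint64_t b = v % m;
    bits[b >> 6] |= (1ULL << (b & 63));
  }
  bool get(uint64_t v) const {
    uint64_t b = v % m;
    return (bits[b >> 6] >> (b & 63)) & 1ULL;
  }
  uint64_t set_bits() const {
    uint64_t n = 0;
    for (uint64_t w : bits) n += popcount64(w);
    return n;
  }
};

static BloomF* get_bf(SEXP ptr) {
  XPtr<BloomF> p(ptr);
  if (!p) Rcpp::stop("invalid Bloom filter pointer");
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_bloom_new(double m, int h) {
  if (m < 1) stop("m must be >= 1");
  if (h < 1) stop("h must be >= 1");
  XPtr<BloomF> p(new BloomF((uint64_t)m, (uint64_t)h), true);
  return p;
}

// [[Rcpp::export]]
List cpp_bloom_info(SEXP ptr) {
  BloomF* bf = get_bf(ptr);
  return List::create(_["m"] = (double)bf->m, _["h"] = (int)bf->h,
                      _["n_inserted"] = (double)bf->n_inserted,
                      _["set_bits"] = (double)bf->set_bits());
}

static std::vector<uint64_t> parse_row(const CharacterMatrix& hx, R_xlen_t i) {
  std::vector<uint64_t> v(hx.ncol());
  for (int j = 0; j < hx.ncol(); ++j)
    v[j] = hex_to_u64(as<std::string>(hx(i, j)));
  return v;
}

// [[Rcpp::export]]
void cpp_bloom_insert(SEXP ptr, CharacterMatrix hashes) {
  BloomF* bf = get_bf(ptr);
  if ((uint64_t)hashes.ncol() != bf->h)
    stop("expected %d hash values per element, got %d", (int)bf->h, hashes.ncol());
  for (R_xlen_t i = 0; i < hashes.nrow(); ++i) {
    for (uint64_t v : parse_row(hashes, i)) bf->set(v);
    bf->n_inserted++;
  }
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_contains(SEXP ptr, CharacterMatrix hashes) {
  BloomF* bf = get_bf(ptr);
  if ((uint64_t)hashes.ncol() != bf->h)
    stop("expected %d hash values per element, got %d", (int)bf->h, hashes.ncol());
  LogicalVector out(hashes.nrow());
  for (R_xlen_t i = 0; i < hashes.nrow(); ++i) {
    bool all = true;
    for (uint64_t v : parse_row(hashes, i))
      if (!bf->get(v)) { all = false; break; }
    out[i] = all;
  }
  return out;
}

// streaming fast paths: hash sequences at level `seeds`, expand to bf->h
// hashes per k-mer, insert / count hits
static uint64_t multi_ok(BloomF* bf, uint64_t base, int k, bool insert) {
  if (insert) {
    bf->set(base);
    for (uint64_t j = 1; j < bf->h; ++j) bf->set(multi_hash_i(base, j, (uint64_t)k));
    return 1;
  }
  if (!bf->get(base)) return 0;
  for (uint64_t j = 1; j < bf->h; ++j)
    if (!bf->get(multi_hash_i(base, j, (uint64_t)k))) return 0;
  return 1;
}

// shared scan (duplicated template from hashcore kept local to avoid a
// header dependency on Rcpp types)
template <typename EMIT>
static void scan_seq(const std::string& seq, int k,
                     const std::array<uint64_t, NAA>& tab, EMIT emit) {
  const char* s = seq.c_str();
  R_xlen_t L = (R_xlen_t)seq.size();
  R_xlen_t p = 0;
  bool prev_valid = false;
  uint64_t H = 0;
  while (p + k <= L) {
    if (!prev_valid) {
      R_xlen_t bad = -1;
      for (R_xlen_t j = p; j < p + k; ++j)
        if (aa_index(s[j]) < 0) bad = j;
      if (bad >= 0) { p = bad + 1; continue; }
      H = 0;
      for (int j = 0; j < k; ++j)
        H ^= srol_n(tab[aa_index(s[p + j])], (uint64_t)(k - 1 - j));
    } else {
      int ii = aa_index(s[p + k - 1]);
      if (ii < 0) { prev_valid = false; p = p + k; continue; }
      H = srol1(H) ^ srol_n(tab[aa_index(s[p - 1])], (uint64_t)k) ^ tab[ii];
    }
    emit(H);
    prev_valid = true;
    ++p;
  }
}

static std::array<uint64_t, NAA> parse_tab(const CharacterVector& seeds) {
  if (seeds.size() != NAA) stop("seed table must have exactly %d entries", NAA);
  std::array<uint64_t, NAA> tab;
  for (int i = 0; i < NAA; ++i) tab[i] = hex_to_u64(as<std::string>(seeds[i]));
  return tab;
}

// [[Rcpp::export]]
double cpp_bloom_insert_seqs(SEXP ptr, CharacterVector seqs, int k, CharacterVector seeds) {
  BloomF* bf = get_bf(ptr);
  auto tab = parse_tab(seeds);
  double n = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    scan_seq(s, k, tab, [&](uint64_t H) {
      multi_ok(bf, H, k, true);
      bf->n_inserted++;
      n += 1;
    });
  }
  return n;
}

// [[Rcpp::export]]
NumericVector cpp_bloom_query_seqs(SEXP ptr, CharacterVector seqs, int k, CharacterVector seeds) {
  BloomF* bf = get_bf(ptr);
  auto tab = parse_tab(seeds);
  double n = 0, hits = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    scan_seq(s, k, tab, [&](uint64_t H) {
      n += 1;
      hits += multi_ok(bf, H, k, false);
    });
  }
  return NumericVector::create(n, hits);
}

// [[Rcpp::export]]
IntegerVector cpp_bloom_set_positions(SEXP ptr) {
  BloomF* bf = get_bf(ptr);
  if (bf->m > 1000000) stop("set-position listing is for small filters only");
  std::vector<int> pos;
  for (uint64_t b = 0; b < bf->m; ++b)
    if ((bf->bits[b >> 6] >> (b & 63)) & 1ULL) pos.push_back((int)b);
  return wrap(pos);
}

// little-endian on-disk layout: magic "PHBF", u32 version, u64 m, h,
// n_inserted, then ceil(m/64) u64 words
static void put_u64(FILE* f, uint64_t v) {
  unsigned char b[8];
  for (int i = 0; i < 8; ++i) b[i] = (v >> (8 * i)) & 0xFF;
  if (fwrite(b, 1, 8, f) != 8) { fclose(f); stop("write failed"); }
}
static uint64_t take_u64(FILE* f) {
  unsigned char b[8];
  if (fread(b, 1, 8, f) != 8) { fclose(f); stop("truncated Bloom filter file"); }
  uint64_t v = 0;
  for (int i = 7; i >= 0; --i) v = (v << 8) | b[i];
  return v;
}

// [[Rcpp::export]]
void cpp_bloom_save(SEXP ptr, std::string path) {
  BloomF* bf = get_bf(ptr);
  FILE* f = fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  const unsigned char magic[4] = {'P', 'H', 'B', 'F'};
  unsigned char ver[4] = {1, 0, 0, 0};
  fwrite(magic, 1, 4, f);
  fwrite(ver, 1, 4, f);
  put_u64(f, bf->m);
  put_u64(f, bf->h);
  put_u64(f, bf->n_inserted);
  for (uint64_t w : bf->bits) put_u64(f, w);
  fclose(f);
}

// [[Rcpp::export]]
SEXP cpp_bloom_load(std::string path) {
  FILE* f = fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  unsigned char hdr[8];
  if (fread(hdr, 1, 8, f) != 8 || hdr[0] != 'P' || hdr[1] != 'H' ||
      hdr[2] != 'B' || hdr[3] != 'F') {
    fclose(f);
    stop("'%s' is not a Bloom filter file", path.c_str());
  }
  uint64_t m = take_u64(f), h = take_u64(f), n_ins = take_u64(f);
  XPtr<BloomF> p(new BloomF(m, h), true);
  p->n_inserted = n_ins;
  for (size_t i = 0; i < p->bits.size(); ++i) p->bits[i] = take_u64(f);
  fclose(f);
  return p;
}
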