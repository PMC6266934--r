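// Hash kernels. All hash values are 64-bit unsigned integers; R has no
// native uint64, so values cross the R boundary as decimal strings and every
// shift/OR/rotate happens here.
#include <Rcpp.h>
#include <cctype>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
#include <string>
#include <vector>
using namespace Rcpp;

static inline std::string u64_dec(uint64_t v) {
  char buf[24];
  std::snprintf(buf, sizeof buf, "%llu", (unsigned long long)v);
  return std::string(buf);
}

static inline uint64_t dec_u64(const CharacterVector& h, R_xlen_t i) {
  const char* s = CHAR(STRING_ELT(h, i));
  uint64_t v = 0;
  for (; *s >= '0' && *s <= '9'; ++s) v = v * 10u + (uint64_t)(*s - '0');
  return v;
}

static std::vector<uint64_t> parse_hashes(const CharacterVector& h) {
  std::vector<uint64_t> out(h.size());
  for (R_xlen_t i = 0; i < h.size(); ++i) out[i] = dec_u64(h, i);
  return out;
}

static inline uint64_t rotl64(uint64_t x, int r) {
  r &= 63;
  if (r == 0) return x;
  return (x << r) | (x >> (64 - r));
}

// 2-bit encoding: A=00, C=01, G=10, T=11 (U treated as T, case-insensitive).
// Anything else gets code 0 and valid = FALSE.
// [[Rcpp::export]]
List cpp_encode(std::string s) {
  R_xlen_t n = (R_xlen_t)s.size();
  IntegerVector codes(n);
  LogicalVector valid(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = std::toupper((unsigned char)s[i]);
    int code = 0;
    bool ok = true;
    switch (c) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'U':
      case 'T': code = 3; break;
      default: ok = false;
    }
    codes[i] = code;
    valid[i] = ok;
  }
  return List::create(_["codes"] = codes, _["valid"] = valid);
}

// Per-position spaced-seed hash: OR over match offsets of code << shift,
// where shift = 2 * (number of match positions to the left).
// [[Rcpp::export]]
List cpp_naive_stream(IntegerVector codes, LogicalVector valid,
                      IntegerVector offsets, IntegerVector shifts, int span) {
  R_xlen_t n = codes.size();
  R_xlen_t m = n - span + 1;
  if (m < 0) m = 0;
  int w = offsets.size();
  CharacterVector out(m);
  LogicalVector ov(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t h = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      R_xlen_t p = i + offsets[j];
      h |= (uint64_t)codes[p] << shifts[j];
      ok = ok && valid[p];
    }
    out[i] = u64_dec(h);
    ov[i] = ok;
  }
  return List::create(_["hashes"] = out, _["valid"] = ov);
}

// Rolling k-mer table: first window symbol by symbol, then
// h[i+1] = (h[i] >> 2) | (code[i+l] << 2(l-1)). Window validity is tracked
// with a running count of invalid symbols.
// [[Rcpp::export]]
List cpp_kmer_table(IntegerVector codes, LogicalVector valid, int l) {
  R_xlen_t n = codes.size();
  R_xlen_t m = n - l + 1;
  CharacterVector out(m);
  LogicalVector ov(m);
  uint64_t h = 0;
  int bad = 0;
  for (int j = 0; j < l; ++j) {
    h |= (uint64_t)codes[j] << (2 * j);
    if (!valid[j]) ++bad;
  }
  out[0] = u64_dec(h);
  ov[0] = (bad == 0);
  for (R_xlen_t i = 1; i < m; ++i) {
    h = (h >> 2) | ((uint64_t)codes[i + l - 1] << (2 * (l - 1)));
    if (!valid[i - 1]) --bad;
    if (!valid[i + l - 1]) ++bad;
    out[i] = u64_dec(h);
    ov[i] = (bad == 0);
  }
  return List::create(_["hashes"] = out, _["valid"] = ov);
}

// Recombine block hashes looked up in the k-mer tables:
// h(i) = OR over blocks j of T_{l_j}[i + b_j] << 2*m(b_j).
// `tables`/`tvalid` hold one entry per *distinct* block length;
// `block_tab` maps each block to its table (0-based).
// [[Rcpp::export]]
List cpp_fish_stream(List tables, List tvalid, IntegerVector block_tab,
                     IntegerVector starts, IntegerVector shifts,
                     int span, int n) {
  int nt = tables.size();
  std::vector<std::vector<uint64_t> > th(nt);
  std::vector<LogicalVector> tv(nt);
  for (int t = 0; t < nt; ++t) {
    th[t] = parse_hashes(tables[t]);
    tv[t] = as<LogicalVector>(tvalid[t]);
  }
  R_xlen_t m = (R_xlen_t)n - span + 1;
  if (m < 0) m = 0;
  int nb = starts.size();
  CharacterVector out(m);
  LogicalVector ov(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t h = 0;
    bool ok = true;
    for (int b = 0; b < nb; ++b) {
      R_xlen_t p = i + starts[b];
      int t = block_tab[b];
      h |= th[t][p] << shifts[b];
      ok = ok && tv[t][p];
    }
    out[i] = u64_dec(h);
    ov[i] = ok;
  }
  return List::create(_["hashes"] = out, _["valid"] = ov);
}

// Big-endian binary rendering, zero-padded to `width` bits. With the
// first matched symbol in the least-significant bits, this reads the last
// matched symbol's code leftmost.
// [[Rcpp::export]]
CharacterVector cpp_bits(CharacterVector hashes, int width) {
  if (width < 1 || width > 64) stop("bit width must be in 1..64");
  R_xlen_t n = hashes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = dec_u64(hashes, i);
    if (width < 64 && (v >> width) != 0)
      stop("hash value does not fit in the requested bit width");
    std::string s(width, '0');
    for (int b = 0; b < width; ++b)
      if ((v >> b) & 1ULL) s[width - 1 - b] = '1';
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
RawVector cpp_u64_to_raw(CharacterVector hashes) {
  R_xlen_t n = hashes.size();
  RawVector out(8 * n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = dec_u64(hashes, i);
    for (int b = 0; b < 8; ++b) out[8 * i + b] = (Rbyte)((v >> (8 * b)) & 0xFF);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_raw_to_u64(RawVector bytes) {
  if (bytes.size() % 8 != 0) stop("byte payload is not a multiple of 8");
  R_xlen_t n = bytes.size() / 8;
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = 0;
    for (int b = 0; b < 8; ++b) v |= (uint64_t)bytes[8 * i + b] << (8 * b);
    out[i] = u64_dec(v);
  }
  return out;
}

// splitmix64: a tiny, platform-independent PRNG used only to derive the
// 4-entry salt table of the cyclic-polynomial variant from an integer seed.
static inline uint64_t splitmix64(uint64_t& state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
CharacterVector cpp_salt_table(int rng_seed) {
  uint64_t state = (uint64_t)(int64_t)rng_seed;
  uint64_t v[4];
  for (int i = 0; i < 4;) {
    uint64_t x = splitmix64(state);
    bool dup = false;
    for (int j = 0; j < i; ++j) dup = dup || (v[j] == x);
    if (!dup) v[i++] = x;
  }
  CharacterVector out(4);
  for (int i = 0; i < 4; ++i) out[i] = u64_dec(v[i]);
  return out;
}

// Cyclic-polynomial per-position hash: XOR over match offsets of
// rotl64(salt[code], rot), rot = m(k) mod 64.
// [[Rcpp::export]]
List cpp_cyclic_naive(IntegerVector codes, LogicalVector valid,
                      IntegerVector offsets, IntegerVector rots,
                      CharacterVector salt, int span) {
  std::vector<uint64_t> sv = parse_hashes(salt);
  R_xlen_t n = codes.size();
  R_xlen_t m = n - span + 1;
  if (m < 0) m = 0;
  int w = offsets.size();
  CharacterVector out(m);
  LogicalVector ov(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t h = 0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      R_xlen_t p = i + offsets[j];
      h ^= rotl64(sv[codes[p]], rots[j]);
      ok = ok && valid[p];
    }
    out[i] = u64_dec(h);
    ov[i] = ok;
  }
  return List::create(_["hashes"] = out, _["valid"] = ov);
}

// Cyclic k-mer table with rotation amount = within-window index:
// H(i) = XOR_{j<l} rotl(salt[x_{i+j}], j), rolled as
// H(i+1) = rotr(H(i) ^ salt[x_i], 1) ^ rotl(salt[x_{i+l}], l-1).
// [[Rcpp::export]]
List cpp_cyclic_kmer_table(IntegerVector codes, LogicalVector valid, int l,
                           CharacterVector salt) {
  std::vector<uint64_t> sv = parse_hashes(salt);
  R_xlen_t n = codes.size();
  R_xlen_t m = n - l + 1;
  CharacterVector out(m);
  LogicalVector ov(m);
  uint64_t h = 0;
  int bad = 0;
  for (int j = 0; j < l; ++j) {
    h ^= rotl64(sv[codes[j]], j);
    if (!valid[j]) ++bad;
  }
  out[0] = u64_dec(h);
  ov[0] = (bad == 0);
  for (R_xlen_t i = 1; i < m; ++i) {
    h = rotl64(h ^ sv[codes[i - 1]], 63) ^ rotl64(sv[codes[i + l - 1]], l - 1);
    if (!valid[i - 1]) --bad;
    if (!valid[i + l - 1]) ++bad;
    out[i] = u64_dec(h);
    ov[i] = (bad == 0);
  }
  return List::create(_["hashes"] = out, _["valid"] = ov);
}

// Cyclic recombination: XOR over blocks of rotl(T_{l_j}[i+b_j], m(b_j) mod 64).
// [[Rcpp::export]]
List cpp_cyclic_combine(List tables, List tvalid, IntegerVector block_tab,
                        IntegerVector starts, IntegerVector rots,
                        int span, int n) {
  int nt = tables.size();
  std::vector<std::vector<uint64_t> > th(nt);
  std::vector<LogicalVector> tv(nt);
  for (int t = 0; t < nt; ++t) {
    th[t] = parse_hashes(tables[t]);
    tv[t] = as<LogicalVector>(tvalid[t]);
  }
  R_xlen_t m = (R_xlen_t)n - span + 1;
  if (m < 0) m = 0;
  int nb = starts.size();
  CharacterVector out(m);
  LogicalVector ov(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t h = 0;
    bool ok = true;
    for (int b = 0; b < nb; ++b) {
      R_xlen_t p = i + starts[b];
      int t = block_tab[b];
      h ^= rotl64(th[t][p], rots[b]);
      ok = ok && tv[t][p];
    }
    out[i] = u64_dec(h);
    ov[i] = ok;
  }
  return List::create(_["hashes"] = out, _["valid"] = ov);
}
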