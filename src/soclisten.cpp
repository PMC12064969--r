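#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cctype>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// SHA-256 (FIPS 180-4), self-contained. Used as the keyed one-way hash behind
// identifier obfuscation: token = base36(first 64 bits of SHA256(salt|0x1f|value)).
// ---------------------------------------------------------------------------

namespace {

inline uint32_t rotr(uint32_t x, uint32_t n) { return (x >> n) | (x << (32 - n)); }

const uint32_t K256[64] = {
  0x428a2f98,0x71374491,0xb5c0fbcf,0xe9b5dba5,0x3956c25b,0x59f111f1,
  0x923f82a4,0xab1c5ed5,0xd807aa98,0x12835b01,0x243185be,0x550c7dc3,
  0x72be5d74,0x80deb1fe,0x9bdc06a7,0xc19bf174,0xe49b69c1,0xefbe4786,
  0x0fc19dc6,0x240ca1cc,0x2de92c6f,0x4a7484aa,0x5cb0a9dc,0x76f988da,
  0x983e5152,0xa831c66d,0xb00327c8,0xbf597fc7,0xc6e00bf3,0xd5a79147,
  0x06ca6351,0x14292967,0x27b70a85,0x2e1b2138,0x4d2c6dfc,0x53380d13,
  0x650a7354,0x766a0abb,0x81c2c92e,0x92722c85,0xa2bfe8a1,0xa81a664b,
  0xc24b8b70,0xc76c51a3,0xd192e819,0xd6990624,0xf40e3585,0x106aa070,
  0x19a4c116,0x1e376c08,0x2748774c,0x34b0bcb5,0x391c0cb3,0x4ed8aa4a,
  0x5b9cca4f,0x682e6ff3,0x748f82ee,0x78a5636f,0x84c87814,0x8cc70208,
  0x90befffa,0xa4506ceb,0xbef9a3f7,0xc67178f2
};

struct Sha256 {
  uint32_t h[8];
  uint8_t buf[64];
  uint64_t len;
  size_t fill;

  Sha256() {
    static const uint32_t init[8] = {
      0x6a09e667,0xbb67ae85,0x3c6ef372,0xa54ff53a,
      0x510e527f,0x9b05688c,0x1f83d9ab,0x5be0cd19
    };
    std::memcpy(h, init, sizeof(h));
    len = 0; fill = 0;
  }

  void block(const uint8_t* p) {
    uint32_t w[64];
    for (int i = 0; i < 16; ++i)
      w[i] = (uint32_t(p[4*i]) << 24) | (uint32_t(p[4*i+1]) << 16) |
             (uint32_t(p[4*i+2]) << 8) | uint32_t(p[4*i+3]);
    for (int i = 16; i < 64; ++i) {
      uint32_t s0 = rotr(w[i-15], 7) ^ rotr(w[i-15], 18) ^ (w[i-15] >> 3);
      uint32_t s1 = rotr(w[i-2], 17) ^ rotr(w[i-2], 19) ^ (w[i-2] >> 10);
      w[i] = w[i-16] + s0 + w[i-7] + s1;
    }
    uint32_t a=h[0],b=h[1],c=h[2],d=h[3],e=h[4],f=h[5],g=h[6],hh=h[7];
    for (int i = 0; i < 64; ++i) {
      uint32_t S1 = rotr(e,6) ^ rotr(e,11) ^ rotr(e,25);
      uint32_t ch = (e & f) ^ (~e & g);
      uint32_t t1 = hh + S1 + ch + K256[i] + w[i];
      uint32_t S0 = rotr(a,2) ^ rotr(a,13) ^ rotr(a,22);
      uint32_t maj = (a & b) ^ (a & c) ^ (b & c);
      uint32_t t2 = S0 + maj;
      hh=g; g=f; f=e; e=d+t1; d=c; c=b; b=a; a=t1+t2;
    }
    h[0]+=a; h[1]+=b; h[2]+=c; h[3]+=d; h[4]+=e; h[5]+=f; h[6]+=g; h[7]+=hh;
  }

  void update(const uint8_t* p, size_t n) {
    len += n;
    while (n > 0) {
      size_t take = std::min(n, 64 - fill);
      std::memcpy(buf + fill, p, take);
      fill += take; p += take; n -= take;
      if (fill == 64) { block(buf); fill = 0; }
    }
  }

  void final(uint8_t out[32]) {
    uint64_t bits = len * 8;
    uint8_t pad = 0x80;
    update(&pad, 1);
    uint8_t zero = 0;
    while (fill != 56) update(&zero, 1);
    uint8_t lenb[8];
    for (int i = 0; i < 8; ++i) lenb[i] = uint8_t(bits >> (8 * (7 - i)));
    update(lenb, 8);
    for (int i = 0; i < 8; ++i) {
      out[4*i]   = uint8_t(h[i] >> 24);
      out[4*i+1] = uint8_t(h[i] >> 16);
      out[4*i+2] = uint8_t(h[i] >> 8);
      out[4*i+3] = uint8_t(h[i]);
    }
  }
};

const char B36[] = "0123456789abcdefghijklmnopqrstuvwxyz";

} // namespace

// [[Rcpp::export(name = ".hash_base36")]]
CharacterVector hash_base36(CharacterVector values, std::string salt, int token_length) {
  if (token_length < 1 || token_length > 12)
    stop("token_length must be between 1 and 12");
  R_xlen_t n = values.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(values[i])) { out[i] = NA_STRING; continue; }
    std::string v = as<std::string>(values[i]);
    Sha256 s;
    s.update(reinterpret_cast<const uint8_t*>(salt.data()), salt.size());
    uint8_t sep = 0x1f;  // unit separator: keeps (salt, value) unambiguous
    s.update(&sep, 1);
    s.update(reinterpret_cast<const uint8_t*>(v.data()), v.size());
    uint8_t digest[32];
    s.final(digest);
    uint64_t x = 0;
    for (int b = 0; b < 8; ++b) x = (x << 8) | digest[b];
    std::string tok(token_length, '0');
    for (int d = token_length - 1; d >= 0; --d) { tok[d] = B36[x % 36]; x /= 36; }
    out[i] = tok;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Levenshtein distance, unit-cost insert/delete/substitute, two-row DP.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".levenshtein")]]
IntegerVector levenshtein(CharacterVector a, CharacterVector b, bool case_insensitive) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1) stop("lengths of a and b must match or be 1");
  if (b.size() != n && b.size() != 1) stop("lengths of a and b must match or be 1");
  IntegerVector out(n);
  std::vector<int> prev, cur;
  for (R_xlen_t i = 0; i < n; ++i) {
    String sa = a.size() == 1 ? a[0] : a[i];
    String sb = b.size() == 1 ? b[0] : b[i];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_INTEGER; continue; }
    std::string x = sa.get_cstring(), y = sb.get_cstring();
    if (case_insensitive) {
      for (auto& c : x) c = std::tolower(static_cast<unsigned char>(c));
      for (auto& c : y) c = std::tolower(static_cast<unsigned char>(c));
    }
    size_t lx = x.size(), ly = y.size();
    prev.assign(ly + 1, 0); cur.assign(ly + 1, 0);
    for (size_t j = 0; j <= ly; ++j) prev[j] = int(j);
    for (size_t ii = 1; ii <= lx; ++ii) {
      cur[0] = int(ii);
      for (size_t j = 1; j <= ly; ++j) {
        int sub = prev[j-1] + (x[ii-1] == y[j-1] ? 0 : 1);
        cur[j] = std::min(std::min(prev[j] + 1, cur[j-1] + 1), sub);
      }
      std::swap(prev, cur);
    }
    out[i] = prev[ly];
  }
  return out;
}
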