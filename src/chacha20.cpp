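// ChaCha20 stream cipher, original construction: 256-bit key, 64-bit nonce,
// 64-bit block counter. Encryption and decryption are the same XOR operation.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

static inline uint32_t rotl32(uint32_t x, int n) { return (x << n) | (x >> (32 - n)); }

#define CC_QR(a, b, c, d)                                     \
  a += b; d ^= a; d = rotl32(d, 16);                          \
  c += d; b ^= c; b = rotl32(b, 12);                          \
  a += b; d ^= a; d = rotl32(d, 8);                           \
  c += d; b ^= c; b = rotl32(b, 7);

static void chacha20_block(const uint32_t key[8], uint64_t counter,
                           const uint32_t nonce[2], uint8_t out[64]) {
  uint32_t s[16], x[16];
  s[0] = 0x61707865u; s[1] = 0x3320646eu; s[2] = 0x79622d32u; s[3] = 0x6b206574u;
  for (int i = 0; i < 8; ++i) s[4 + i] = key[i];
  s[12] = (uint32_t)(counter & 0xffffffffu);
  s[13] = (uint32_t)(counter >> 32);
  s[14] = nonce[0];
  s[15] = nonce[1];
  std::memcpy(x, s, sizeof s);
  for (int r = 0; r < 10; ++r) {
    CC_QR(x[0], x[4], x[8],  x[12])
    CC_QR(x[1], x[5], x[9],  x[13])
    CC_QR(x[2], x[6], x[10], x[14])
    CC_QR(x[3], x[7], x[11], x[15])
    CC_QR(x[0], x[5], x[10], x[15])
    CC_QR(x[1], x[6], x[11], x[12])
    CC_QR(x[2], x[7], x[8],  x[13])
    CC_QR(x[3], x[4], x[9],  x[14])
  }
  for (int i = 0; i < 16; ++i) {
    uint32_t v = x[i] + s[i];
    out[4 * i]     = (uint8_t)(v & 0xff);
    out[4 * i + 1] = (uint8_t)((v >> 8) & 0xff);
    out[4 * i + 2] = (uint8_t)((v >> 16) & 0xff);
    out[4 * i + 3] = (uint8_t)((v >> 24) & 0xff);
  }
}

static inline uint32_t load_le32(const uint8_t* p) {
  return (uint32_t)p[0] | ((uint32_t)p[1] << 8) | ((uint32_t)p[2] << 16) |
         ((uint32_t)p[3] << 24);
}

// [[Rcpp::export(name = ".chacha20_xor")]]
RawVector chacha20_xor_(RawVector data, RawVector key, RawVector nonce,
                        double counter = 0) {
  if (key.size() != 32) stop("key must be exactly 32 bytes");
  if (nonce.size() != 8) stop("nonce must be exactly 8 bytes");
  if (counter < 0) stop("counter must be non-negative");
  uint32_t k[8], n[2];
  for (int i = 0; i < 8; ++i) k[i] = load_le32(&key[4 * i]);
  for (int i = 0; i < 2; ++i) n[i] = load_le32(&nonce[4 * i]);
  RawVector out(data.size());
  uint64_t ctr = (uint64_t)counter;
  uint8_t ks[64];
  R_xlen_t i = 0;
  while (i < data.size()) {
    chacha20_block(k, ctr++, n, ks);
    R_xlen_t blk = std::min((R_xlen_t)64, data.size() - i);
    for (R_xlen_t j = 0; j < blk; ++j) out[i + j] = data[i + j] ^ ks[j];
    i += blk;
  }
  return out;
}
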