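// BLAKE3 cryptographic hash (plain and keyed modes) with extendable output
// up to 64 bytes, which covers every digest length this protocol uses
// (2-byte header fingerprints, 8-byte derived nonces, 32-byte subkeys).
// Non-incremental: the whole message is available, so the chunk tree is
// built recursively (left subtree = largest power-of-two number of chunks
// strictly smaller than the total).
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

static const uint32_t B3_IV[8] = {
  0x6a09e667u, 0xbb67ae85u, 0x3c6ef372u, 0xa54ff53au,
  0x510e527fu, 0x9b05688cu, 0x1f83d9abu, 0x5be0cd19u
};

enum {
  CHUNK_START = 1 << 0,
  CHUNK_END   = 1 << 1,
  PARENT      = 1 << 2,
  ROOT        = 1 << 3,
  KEYED_HASH  = 1 << 4
};

static const int B3_PERM[16] = {2, 6, 3, 10, 7, 0, 4, 13, 1, 11, 12, 5, 9, 14, 15, 8};

static inline uint32_t rotr32(uint32_t x, int n) { return (x >> n) | (x << (32 - n)); }

static inline void g(uint32_t* v, int a, int b, int c, int d, uint32_t mx, uint32_t my) {
  v[a] = v[a] + v[b] + mx;
  v[d] = rotr32(v[d] ^ v[a], 16);
  v[c] = v[c] + v[d];
  v[b] = rotr32(v[b] ^ v[c], 12);
  v[a] = v[a] + v[b] + my;
  v[d] = rotr32(v[d] ^ v[a], 8);
  v[c] = v[c] + v[d];
  v[b] = rotr32(v[b] ^ v[c], 7);
}

static void compress(const uint32_t cv[8], const uint32_t block[16], uint64_t counter,
                     uint32_t block_len, uint32_t flags, uint32_t out[16]) {
  uint32_t v[16], m[16], tmp[16];
  for (int i = 0; i < 8; ++i) v[i] = cv[i];
  for (int i = 0; i < 4; ++i) v[8 + i] = B3_IV[i];
  v[12] = (uint32_t)(counter & 0xffffffffu);
  v[13] = (uint32_t)(counter >> 32);
  v[14] = block_len;
  v[15] = flags;
  std::memcpy(m, block, sizeof m);
  for (int r = 0; r < 7; ++r) {
    g(v, 0, 4, 8,  12, m[0],  m[1]);
    g(v, 1, 5, 9,  13, m[2],  m[3]);
    g(v, 2, 6, 10, 14, m[4],  m[5]);
    g(v, 3, 7, 11, 15, m[6],  m[7]);
    g(v, 0, 5, 10, 15, m[8],  m[9]);
    g(v, 1, 6, 11, 12, m[10], m[11]);
    g(v, 2, 7, 8,  13, m[12], m[13]);
    g(v, 3, 4, 9,  14, m[14], m[15]);
    if (r < 6) {
      for (int i = 0; i < 16; ++i) tmp[i] = m[B3_PERM[i]];
      std::memcpy(m, tmp, sizeof m);
    }
  }
  for (int i = 0; i < 8; ++i) {
    out[i] = v[i] ^ v[i + 8];
    out[i + 8] = v[i + 8] ^ cv[i];
  }
}

// Pending final compression, kept open so the ROOT flag (and XOF counter)
// can be applied at the very end.
struct B3Output {
  uint32_t cv[8];
  uint32_t block[16];
  uint64_t counter;
  uint32_t block_len;
  uint32_t flags;
};

static void words_from_bytes(const uint8_t* p, size_t n, uint32_t out[16]) {
  uint8_t buf[64];
  std::memset(buf, 0, 64);
  std::memcpy(buf, p, n);
  for (int i = 0; i < 16; ++i)
    out[i] = (uint32_t)buf[4 * i] | ((uint32_t)buf[4 * i + 1] << 8) |
             ((uint32_t)buf[4 * i + 2] << 16) | ((uint32_t)buf[4 * i + 3] << 24);
}

static B3Output chunk_output(const uint8_t* chunk, size_t len, uint64_t chunk_counter,
                             const uint32_t key[8], uint32_t base_flags) {
  uint32_t cv[8];
  std::memcpy(cv, key, sizeof cv);
  // number of 64-byte blocks; an empty chunk still has one zero-length block
  size_t nblocks = len == 0 ? 1 : (len + 63) / 64;
  uint32_t out[16];
  for (size_t b = 0; b + 1 < nblocks; ++b) {
    uint32_t block[16];
    words_from_bytes(chunk + 64 * b, 64, block);
    uint32_t flags = base_flags | (b == 0 ? CHUNK_START : 0);
    compress(cv, block, chunk_counter, 64, flags, out);
    std::memcpy(cv, out, 8 * sizeof(uint32_t));
  }
  B3Output o;
  std::memcpy(o.cv, cv, sizeof o.cv);
  size_t last_off = 64 * (nblocks - 1);
  size_t last_len = len - last_off;
  words_from_bytes(chunk + last_off, last_len, o.block);
  o.counter = chunk_counter;
  o.block_len = (uint32_t)last_len;
  o.flags = base_flags | (nblocks == 1 ? CHUNK_START : 0) | CHUNK_END;
  return o;
}

static void output_cv(const B3Output& o, uint32_t cv[8]) {
  uint32_t out[16];
  compress(o.cv, o.block, o.counter, o.block_len, o.flags, out);
  std::memcpy(cv, out, 8 * sizeof(uint32_t));
}

static B3Output parent_output(const uint32_t l[8], const uint32_t r[8],
                              const uint32_t key[8], uint32_t base_flags) {
  B3Output o;
  std::memcpy(o.cv, key, sizeof o.cv);
  for (int i = 0; i < 8; ++i) { o.block[i] = l[i]; o.block[8 + i] = r[i]; }
  o.counter = 0;
  o.block_len = 64;
  o.flags = base_flags | PARENT;
  return o;
}

static uint64_t left_subtree_chunks(uint64_t n) {
  // largest power of two strictly less than n (n >= 2)
  uint64_t p = 1;
  while (p * 2 < n) p *= 2;
  return p;
}

static B3Output subtree_output(const uint8_t* data, size_t len, uint64_t chunk_counter,
                               const uint32_t key[8], uint32_t base_flags) {
  if (len <= 1024)
    return chunk_output(data, len, chunk_counter, key, base_flags);
  uint64_t nchunks = (len + 1023) / 1024;
  uint64_t lchunks = left_subtree_chunks(nchunks);
  size_t llen = (size_t)lchunks * 1024;
  B3Output lo = subtree_output(data, llen, chunk_counter, key, base_flags);
  B3Output ro = subtree_output(data + llen, len - llen, chunk_counter + lchunks,
                               key, base_flags);
  uint32_t lcv[8], rcv[8];
  output_cv(lo, lcv);
  output_cv(ro, rcv);
  return parent_output(lcv, rcv, key, base_flags);
}

// [[Rcpp::export(name = ".blake3_hash")]]
RawVector blake3_hash_(RawVector data, Nullable<RawVector> key = R_NilValue,
                       int out_len = 32) {
  if (out_len < 1 || out_len > 64) stop("out_len must be between 1 and 64");
  uint32_t kw[8];
  uint32_t base_flags = 0;
  if (key.isNotNull()) {
    RawVector k(key);
    if (k.size() != 32) stop("key must be exactly 32 bytes");
    for (int i = 0; i < 8; ++i)
      kw[i] = (uint32_t)k[4 * i] | ((uint32_t)k[4 * i + 1] << 8) |
              ((uint32_t)k[4 * i + 2] << 16) | ((uint32_t)k[4 * i + 3] << 24);
    base_flags = KEYED_HASH;
  } else {
    std::memcpy(kw, B3_IV, sizeof kw);
  }
  const uint8_t* p = data.size() ? (const uint8_t*)&data[0] : (const uint8_t*)"";
  B3Output root = subtree_output(p, (size_t)data.size(), 0, kw, base_flags);
  // root finalization; one compression yields 64 output bytes (16 words)
  uint32_t out[16];
  compress(root.cv, root.block, 0, root.block_len, root.flags | ROOT, out);
  RawVector res(out_len);
  for (int i = 0; i < out_len; ++i)
    res[i] = (uint8_t)((out[i / 4] >> (8 * (i % 4))) & 0xff);
  return res;
}
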