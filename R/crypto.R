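#' BLAKE3 hash (plain or keyed), truncated to any length up to 64 bytes
#'
#' @param data raw vector to hash.
#' @param key optional 32-byte raw vector; when given the keyed mode is used.
#' @param length output length in bytes (1-64). Truncation is a prefix: the
#'   first `n` bytes of a longer digest equal the `n`-byte digest.
#' @return Raw vector of `length` bytes.
#' @export
#' @examples
#' raw_to_hex(blake3(charToRaw("abc")))
blake3 <- function(data, key = NULL, length = 32L) {
  if (is.character(data)) data <- charToRaw(data)
  stopifnot(is.raw(data))
  .blake3_hash(data, key, as.integer(length))
}

#' ChaCha20 stream encryption (original 64-bit-nonce construction)
#'
#' XORs the input with the ChaCha20 keystream (20 rounds, 256-bit key,
#' 64-bit nonce, 64-bit block counter). Encryption and decryption are the
#' same operation, and ciphertext length always equals plaintext length —
#' the property that keeps per-packet message expansion down to the 2-byte
#' authentication fingerprint alone.
#'
#' @param data raw vector (plaintext or ciphertext).
#' @param key 32-byte raw vector.
#' @param nonce 8-byte raw vector; must never repeat under one key for two
#'   distinct messages.
#' @param counter initial 64-byte-block counter (default 0).
#' @return Raw vector of the same length as `data`.
#' @export
chacha20_encrypt <- function(data, key, nonce, counter = 0) {
  stopifnot(is.raw(data))
  if (!is.raw(key) || length(key) != 32L) stop_range("key must be 32 bytes")
  if (!is.raw(nonce) || length(nonce) != 8L) stop_range("nonce must be 8 bytes")
  .chacha20_xor(data, key, nonce, counter)
}

#' @rdname chacha20_encrypt
#' @export
chacha20_decrypt <- chacha20_encrypt

#' Deflate-compress a byte stream (gzip framing)
#'
#' Thin deterministic wrapper over zlib via [memCompress()]: the gzip header
#' written by zlib carries a zero timestamp, so equal input yields equal
#' output across calls and machines.
#'
#' @param data raw vector.
#' @return Compressed (resp. decompressed) raw vector.
#' @export
gzip_compress <- function(data) {
  stopifnot(is.raw(data))
  memCompress(data, type = "gzip")
}

#' @rdname gzip_compress
#' @param raw compressed raw vector as produced by [gzip_compress()].
#' @export
gzip_decompress <- function(raw) {
  stopifnot(is.raw(raw))
  memDecompress(raw, type = "gzip")
}

#' Truncated authentication fingerprint of a packet body
#'
#' Computes `BLAKE3(message || UTF-8(identity_id))` truncated to the first
#' `n` bytes. The decoder recomputes the tag with the logged-in user's
#' identifier, so a packet only authenticates for its intended recipient.
#' Under the protocol default n = 2 a forged tag passes with probability
#' 2^-16.
#'
#' @param message raw vector — the ciphertext chunk of one packet.
#' @param identity_id recipient identifier string (exact UTF-8 bytes, no
#'   normalisation).
#' @param n tag length in bytes, 1-64 (protocol v1 fixes 2).
#' @return Raw vector of `n` bytes.
#' @export
fingerprint <- function(message, identity_id, n = 2L) {
  stopifnot(is.raw(message))
  n <- assert_count(n, "n", 1L, 64L)
  id <- enc2utf8(as.character(identity_id))
  blake3(c(message, charToRaw(id)), length = n)
}

#' Derive the per-message ChaCha20 nonce from shared material
#'
#' The header has no nonce field (overhead stays at 2 bytes), so both ends
#' derive the 8-byte nonce deterministically: a subkey is taken as the
#' keyed-BLAKE3 digest of a fixed context label under the shared secret, and
#' the nonce is the first 8 bytes of the keyed-BLAKE3 digest, under that
#' subkey, of the canonical encoding `version (1) || transaction (2, BE) ||
#' count (1)`. Two distinct messages sharing all three header fields would
#' reuse a keystream; see the package vignette for this documented
#' limitation.
#'
#' @param profile a [codec_profile()] (source of the shared secret).
#' @param version,transaction,count header fields of the transmission.
#' @return 8-byte raw nonce.
#' @export
derive_nonce <- function(profile, version, transaction, count) {
  subkey <- blake3(charToRaw("qrstab.nonce.v1"), key = profile$secret, length = 32L)
  msg <- c(int_to_raw_be(version, 1L), int_to_raw_be(transaction, 2L),
           int_to_raw_be(count, 1L))
  blake3(msg, key = subkey, length = 8L)
}

#' Generate a random 256-bit secret key
#'
#' @param seed optional integer; when supplied the key is reproducible.
#' @return 32-byte raw vector.
#' @export
random_secret <- function(seed = NULL) {
  if (is.null(seed)) return(as.raw(sample.int(256L, 32L, replace = TRUE) - 1L))
  with_seed(seed, as.raw(sample.int(256L, 32L, replace = TRUE) - 1L))
}
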