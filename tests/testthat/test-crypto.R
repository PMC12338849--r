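test_that("ChaCha20 reproduces the published keystream vectors", {
  # zero key, zero nonce: keystream blocks 0 and 1 (RFC 8439 appendix A.1;
  # identical for the original 64-bit-nonce variant when the nonce is zero)
  ks <- chacha20_encrypt(raw(128), raw(32), raw(8))
  expect_identical(
    raw_to_hex(ks[1:64]),
    paste0("76b8e0ada0f13d90405d6ae55386bd28bdd219b8a08ded1aa836efcc8b770dc7",
           "da41597c5157488d7724e03fb8d84a376a43b8f41518a11cc387b669b2ee6586"))
  expect_identical(
    raw_to_hex(ks[65:128]),
    paste0("9f07e7be5551387a98ba977c732d080dcb0f29a048e3656912c6533e32ee7aed",
           "29b721769ce64e43d57133b074d839d531ed1f28510afb45ace10a1f4b794d6f"))
  # the counter argument addresses 64-byte blocks
  expect_identical(chacha20_encrypt(raw(64), raw(32), raw(8), counter = 1),
                   ks[65:128])
})

test_that("encryption preserves length and round-trips", {
  key <- random_secret(11)
  nonce <- as.raw(1:8)
  for (n in c(0L, 1L, 63L, 64L, 65L, 10000L)) {
    plain <- as.raw(sample(0:255, n, replace = TRUE))
    cipher <- chacha20_encrypt(plain, key, nonce)
    expect_identical(length(cipher), n)
    expect_identical(chacha20_decrypt(cipher, key, nonce), plain)
  }
  expect_error(chacha20_encrypt(raw(4), raw(16), raw(8)),
               class = "qrstab_range_error")
  expect_error(chacha20_encrypt(raw(4), raw(32), raw(12)),
               class = "qrstab_range_error")
})

test_that("BLAKE3 matches the reference digests and truncates by prefix", {
  expect_identical(
    raw_to_hex(blake3(raw(0))),
    "af1349b9f5f9a1a6a0404dea36dcc9499bcb25c9adc112b7cc9a93cae41f3262")
  expect_identical(
    raw_to_hex(blake3(charToRaw("abc"))),
    "6437b3ac38465133ffb63b75273a8db548c558465d79db03fd359c6cd5bd9d85")
  msg <- charToRaw("truncation is a prefix")
  expect_identical(blake3(msg, length = 2), blake3(msg, length = 64)[1:2])
  # keyed mode differs from plain mode and from other keys
  k1 <- as.raw(0:31); k2 <- as.raw(c(1, 1:31))
  expect_false(identical(blake3(msg, key = k1), blake3(msg)))
  expect_false(identical(blake3(msg, key = k1), blake3(msg, key = k2)))
  # multi-chunk inputs (tree paths) are deterministic and length-sensitive
  big <- as.raw(rep(171, 5000))
  expect_identical(blake3(big), blake3(big))
  expect_false(identical(blake3(big), blake3(big[-1])))
})

test_that("fingerprints separate identities at the expected 2-byte rate", {
  msg <- charToRaw("packet body")
  expect_identical(fingerprint(msg, "alice", 2), fingerprint(msg, "alice", 2))
  expect_identical(length(fingerprint(msg, "alice", 2)), 2L)
  expect_identical(fingerprint(msg, "alice", 2),
                   fingerprint(msg, "alice", 64)[1:2])
  set.seed(99)
  ids <- matrix(replicate(2000, paste(sample(letters, 12, TRUE), collapse = "")),
                ncol = 2)
  same <- vapply(seq_len(nrow(ids)), function(i)
    identical(fingerprint(msg, ids[i, 1], 2), fingerprint(msg, ids[i, 2], 2)),
    logical(1))
  # collision probability per pair is 2^-16; >= 97% distinct is conservative
  expect_gte(mean(!same), 0.97)
})

test_that("gzip wrapper is deterministic and inverts", {
  set.seed(3)
  blob <- as.raw(sample(0:255, 5000, replace = TRUE))
  expect_identical(gzip_decompress(gzip_compress(blob)), blob)
  expect_identical(gzip_compress(blob), gzip_compress(blob))
  runs <- as.raw(rep(7, 10240))
  expect_lt(length(gzip_compress(runs)), 100)
  expect_error(gzip_decompress(as.raw(1:20)))
})

test_that("nonces derive deterministically from shared material + header fields", {
  prof <- qa_profile()
  n1 <- derive_nonce(prof, 1, 746, 2)
  expect_identical(n1, derive_nonce(prof, 1, 746, 2))
  expect_identical(length(n1), 8L)
  expect_false(identical(n1, derive_nonce(prof, 1, 747, 2)))
  expect_false(identical(n1, derive_nonce(prof, 1, 746, 3)))
  expect_false(identical(n1, derive_nonce(prof, 2, 746, 2)))
  # recompute with direct hash invocations over the canonical field encoding
  subkey <- blake3(charToRaw("qrstab.nonce.v1"), key = prof$secret, length = 32)
  canonical <- as.raw(c(1, 2, 234, 2)) # 1 || 746 big-endian || 2
  expect_identical(n1, blake3(canonical, key = subkey, length = 8))
})

test_that("encrypt-and-authenticate adds exactly the 2-byte tag", {
  prof <- qa_profile()
  plain <- as.raw(sample(0:255, 1000, replace = TRUE))
  nonce <- derive_nonce(prof, 1, 100, 1)
  cipher <- chacha20_encrypt(plain, prof$secret, nonce)
  expect_identical(length(cipher) - length(plain), 0L)
  tag <- fingerprint(cipher, "patient", prof$fingerprint_len)
  expect_identical((length(cipher) - length(plain)) + length(tag), 2L)
})
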