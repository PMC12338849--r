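test_that("header packing follows the declared bit layout", {
  h <- message_header(0, 0, 0, count = 1, seq = 0)
  expect_identical(pack_header(h), as.raw(c(0, 0, 0, 0, 0, 0x10)))

  h <- message_header(1, as.raw(c(0xBE, 0xEF)), 745, count = 2, seq = 1)
  expect_identical(unpack_header(pack_header(h)), h)
})

test_that("packed headers match an independent bit-string oracle", {
  # oracle: concatenate the MSB-first bit strings of each field and repack
  bits_of <- function(x, w) as.integer(rev(intToBits(x))[(32 - w + 1):32])
  oracle <- function(h) {
    bits <- c(bits_of(h$version, 8),
              unlist(lapply(as.integer(h$fingerprint), bits_of, w = 8)),
              bits_of(h$transaction, 16),
              bits_of(h$count, 4), bits_of(h$seq, 4))
    as.raw(colSums(matrix(bits, 8) * 2L^(7:0)))
  }
  set.seed(42)
  for (i in 1:1000) {
    count <- sample(1:15, 1)
    h <- message_header(sample(0:255, 1), as.raw(sample(0:255, 2, TRUE)),
                        sample(0:65535, 1), count, sample(count, 1) - 1L)
    expect_identical(pack_header(h), oracle(h))
  }
})

test_that("pack/unpack is a bijection and rejects malformed input", {
  set.seed(7)
  for (i in 1:200) {
    count <- sample(1:15, 1)
    h <- message_header(sample(0:255, 1), sample(0:65535, 1),
                        sample(0:65535, 1), count, sample(count, 1) - 1L)
    expect_identical(unpack_header(pack_header(h)), h)
  }
  expect_error(unpack_header(raw(5)), class = "qrstab_framing_error")
  # all count-nibble-0 final bytes are rejected
  for (low in 0:15)
    expect_error(unpack_header(c(raw(5), as.raw(low))),
                 class = "qrstab_framing_error")
  expect_error(message_header(1, 0, 0, count = 2, seq = 2),
               class = "qrstab_range_error")
  expect_error(message_header(256, 0, 0, 1, 0), class = "qrstab_range_error")
})

test_that("transaction ids count whole days from the tag epoch", {
  expect_identical(encode_transaction("2020-01-01", "2020-01-01"), 0L)
  # 2020 is a leap year; the calendar oracle is base R's Date arithmetic
  expect_identical(encode_transaction("2022-01-16", "2020-01-01"), 746L)
  expect_identical(as.integer(as.Date("2022-01-16") - as.Date("2020-01-01")),
                   746L)
  expect_error(encode_transaction("2019-12-31", "2020-01-01"),
               class = "qrstab_range_error")
  # the 65536th day after the epoch no longer fits 16 bits
  over <- format(as.Date("2020-01-01") + 65536, "%Y-%m-%d")
  expect_error(encode_transaction(over, "2020-01-01"),
               class = "qrstab_range_error")
  expect_identical(
    encode_transaction(format(as.Date("2020-01-01") + 65535), "2020-01-01"),
    65535L)
})

test_that("packet counts equal the greedy slicing oracle", {
  expect_identical(compute_count(1267, 1273, 6), 1L)
  expect_identical(compute_count(1268, 1273, 6), 2L)
  slice_oracle <- function(n, chunk) length(seq(1, n, by = chunk))
  for (n in c(1:50, seq(51, 19000, by = 371), 19005)) {
    expect_identical(compute_count(n, 1273, 6), slice_oracle(n, 1267))
  }
  expect_error(compute_count(0, 1273, 6), class = "qrstab_empty_error")
  expect_error(compute_count(15 * 1267 + 1, 1273, 6),
               class = "qrstab_capacity_error")
})

test_that("compute_count is monotone in body length and capacity", {
  lens <- seq(1, 19000, by = 233)
  counts <- vapply(lens, compute_count, integer(1), qr_capacity = 1273)
  expect_true(all(diff(counts) >= 0))
  caps <- seq(200, 1273, by = 37)
  counts2 <- vapply(caps, function(cp) compute_count(2500, cp), integer(1))
  expect_true(all(diff(counts2) <= 0))
})
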