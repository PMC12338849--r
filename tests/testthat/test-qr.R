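test_that("module counts and printed sizes follow the symbol arithmetic", {
  expect_identical(qr_modules(25), 117L)
  expect_identical(qr_modules(40), 177L)
  expect_identical(qr_modules(1), 21L)
  expect_error(qr_modules(41), class = "qrstab_range_error")

  expect_equal(print_edge_inches(qr_config(25))$inches, 2.5)
  expect_equal(print_edge_inches(qr_config(40))$inches, 3.7)
  e <- print_edge_inches(qr_config(25), include_redundancy = TRUE)
  expect_equal(e$inches, 3.0)
  expect_equal(e$cm, 7.62)
})

test_that("byte capacities match the specification tables", {
  expect_identical(qr_capacity(25, "L"), 1273L)
  expect_identical(qr_capacity(1, "H"), 7L)
  expect_identical(qr_capacity(40, "L"), 2953L)
  # capacity is non-increasing in EC level for every version
  for (v in 1:40) {
    caps <- vapply(c("L", "M", "Q", "H"), qr_capacity, integer(1),
                   version = v)
    expect_true(all(diff(caps) <= 0))
  }
})

test_that("block tables are consistent with symbol geometry for all versions", {
  # independent check: total codewords counted from non-function modules of
  # the built matrix must equal data + error-correction codewords, and the
  # data codewords must match what the capacity implies for the byte-mode
  # header
  for (v in 1:40) {
    total_geom <- qrstab:::qr_total_codewords(v)
    blk <- qrstab:::QR_BLOCKS_L[v, ]
    data_cw <- as.integer(blk[["g1n"]] * blk[["g1d"]] + blk[["g2n"]] * blk[["g2d"]])
    ec_cw <- as.integer((blk[["g1n"]] + blk[["g2n"]]) * blk[["ec"]])
    expect_identical(total_geom, data_cw + ec_cw)
    expect_identical(as.integer(unname(qrstab:::qr_data_codewords(v, "L"))),
                     data_cw)
  }
})

test_that("split_body slices exactly and reassembles losslessly", {
  cfg <- qr_config()
  id <- "patient-001"
  p1 <- split_body(as.raw(1:100), cfg, 1, 500, id)
  expect_length(p1, 1L)
  expect_identical(p1[[1]]$header$seq, 0L)
  expect_identical(p1[[1]]$header$count, 1L)

  set.seed(21)
  cipher <- as.raw(sample(0:255, 1268, replace = TRUE))
  p2 <- split_body(cipher, cfg, 1, 500, id)
  expect_identical(lengths(lapply(p2, `[[`, "body")), c(1267L, 1L))
  expect_identical(do.call(c, lapply(p2, `[[`, "body")), cipher)

  for (n in c(1, 500, 5000, 15000)) {
    x <- as.raw(sample(0:255, n, replace = TRUE))
    ps <- split_body(x, cfg, 1, 500, id)
    expect_identical(do.call(c, lapply(ps, `[[`, "body")), x)
    # every chunk but the last is full
    sz <- lengths(lapply(ps, `[[`, "body"))
    if (length(sz) > 1) expect_true(all(sz[-length(sz)] == 1267L))
    # headers differ only in seq and fingerprint
    expect_identical(unique(vapply(ps, function(p) p$header$transaction,
                                   integer(1))), 500L)
    expect_identical(vapply(ps, function(p) p$header$seq, integer(1)),
                     seq_along(ps) - 1L)
  }
})

test_that("packet wire form is header || body", {
  pk <- split_body(as.raw(1:50), qr_config(), 3, 746, "id")[[1]]
  wire <- packet_bytes(pk)
  expect_identical(wire[1:6], pack_header(pk$header))
  expect_identical(wire[-(1:6)], pk$body)
  expect_identical(parse_packet(wire)$header, pk$header)
})

test_that("rendered symbols decode bit-exactly, up to full capacity", {
  set.seed(31)
  for (v in c(1L, 7L, 10L, 25L)) {
    cfg <- qr_config(version = v)
    cap <- qr_capacity(v, "L")
    for (n in unique(c(1L, cap %/% 2L, cap))) {
      payload <- as.raw(sample(0:255, n, replace = TRUE))
      expect_identical(read_qr(render_qr(payload, cfg)), payload)
    }
  }
})

test_that("renders survive the PNG write/read cycle", {
  pk <- split_body(as.raw(sample(0:255, 800, TRUE)), qr_config(), 1, 99, "x")[[1]]
  img <- render_qr(pk, qr_config())
  path <- withr::local_tempfile(fileext = ".png")
  write_qr_png(img, path)
  expect_identical(read_qr(path), packet_bytes(pk))
})

test_that("unreadable images raise scan errors", {
  expect_error(read_qr(matrix(1, 50, 50)), class = "qrstab_scan_error")
  set.seed(4)
  expect_error(read_qr(matrix(runif(100 * 100), 100)),
               class = "qrstab_scan_error")
  # a damaged symbol must fail the Reed-Solomon check, not return bad bytes
  img <- render_qr(as.raw(1:200), qr_config(version = 10))
  img[150:190, 150:190] <- 1 - img[150:190, 150:190]
  expect_error(read_qr(img), class = "qrstab_scan_error")
})

test_that("payloads above symbol capacity are rejected", {
  expect_error(render_qr(as.raw(seq_len(1274) %% 256), qr_config(25)),
               class = "qrstab_capacity_error")
})
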