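# QR symbol matrix construction and reading (byte mode, EC level L).
# Implements the symbol structure of ISO/IEC 18004: function patterns,
# format/version information with BCH protection, Reed-Solomon block coding
# over GF(2^8) with the 0x11D reduction polynomial, codeword interleaving,
# the two-column zig-zag placement order, and the XOR data masks. The reader
# targets pristine rasters (its own renders or clean scans): it verifies
# Reed-Solomon syndromes rather than correcting errors.

# ---- GF(256) arithmetic ----------------------------------------------------

qr_env <- new.env(parent = emptyenv())

gf_tables <- function() {
  if (!is.null(qr_env$gf_exp)) return(invisible())
  exp_t <- integer(512L)
  log_t <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- x
    log_t[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, 0x11DL), 0xFFL)
  }
  exp_t[256:512] <- exp_t[1:257]
  qr_env$gf_exp <- exp_t
  qr_env$gf_log <- log_t
  invisible()
}

gf_mul <- function(a, b) {
  out <- integer(length(a))
  nz <- a != 0L & b != 0L
  out[nz] <- qr_env$gf_exp[qr_env$gf_log[a[nz] + 1L] +
                           qr_env$gf_log[b[nz] + 1L] + 1L]
  out
}

rs_generator <- function(n_ec) {
  gf_tables()
  key <- as.character(n_ec)
  if (!is.null(qr_env$gen[[key]])) return(qr_env$gen[[key]])
  g <- 1L
  for (i in 0:(n_ec - 1L)) {
    alpha_i <- qr_env$gf_exp[i + 1L]
    ng <- integer(length(g) + 1L)
    ng[seq_along(g)] <- bitwXor(ng[seq_along(g)], gf_mul(g, rep(alpha_i, length(g))))
    ng[seq_along(g) + 1L] <- bitwXor(ng[seq_along(g) + 1L], g)
    g <- ng
  }
  # g is little-endian in power; convert to big-endian coefficient order
  g <- rev(g)
  if (is.null(qr_env$gen)) qr_env$gen <- list()
  qr_env$gen[[key]] <- g
  g
}

rs_encode_block <- function(data, n_ec) {
  g <- rs_generator(n_ec)[-1L] # monic leading coefficient dropped
  rem <- integer(n_ec)
  for (d in data) {
    factor <- bitwXor(rem[1L], d)
    rem <- c(rem[-1L], 0L)
    if (factor != 0L)
      rem <- bitwXor(rem, gf_mul(g, rep(factor, n_ec)))
  }
  rem
}

rs_syndromes_zero <- function(codeword, n_ec) {
  gf_tables()
  for (i in 0:(n_ec - 1L)) {
    alpha_i <- qr_env$gf_exp[i + 1L]
    s <- 0L
    for (c in codeword) s <- bitwXor(gf_mul(s, alpha_i), c)
    if (s != 0L) return(FALSE)
  }
  TRUE
}

# ---- symbol geometry -------------------------------------------------------

# function-module mask and base pattern for a version; cached.
# Returns list(fun = logical matrix (TRUE = function module),
#              base = integer matrix with function pattern values,
#              order = two-column matrix of (row, col) data module positions
#              in placement order, 1-indexed)
qr_geometry <- function(version) {
  key <- as.character(version)
  if (is.null(qr_env$geom)) qr_env$geom <- list()
  if (!is.null(qr_env$geom[[key]])) return(qr_env$geom[[key]])
  n <- 17L + 4L * version
  fun <- matrix(FALSE, n, n)
  base <- matrix(0L, n, n)

  place_finder <- function(r, c) { # r, c: 1-indexed top-left of the 7x7 eye
    for (i in 0:6) for (j in 0:6) {
      v <- as.integer(i %in% c(0L, 6L) | j %in% c(0L, 6L) |
                      (i >= 2L & i <= 4L & j >= 2L & j <= 4L))
      base[r + i, c + j] <<- v
      fun[r + i, c + j] <<- TRUE
    }
  }
  place_finder(1L, 1L)
  place_finder(1L, n - 6L)
  place_finder(n - 6L, 1L)
  # separators (one white ring inside the symbol around each finder)
  sep <- function(rows, cols) { fun[rows, cols] <<- TRUE; base[rows, cols] <<- 0L }
  sep(8L, 1:8);        sep(1:8, 8L)
  sep(8L, (n - 7L):n); sep(1:8, n - 7L)
  sep(n - 7L, 1:8);    sep((n - 7L):n, 8L)
  # timing patterns
  for (k in 9L:(n - 8L)) {
    v <- as.integer(k %% 2L == 1L)
    if (!fun[7L, k]) { base[7L, k] <- v; fun[7L, k] <- TRUE }
    if (!fun[k, 7L]) { base[k, 7L] <- v; fun[k, 7L] <- TRUE }
  }
  # alignment patterns
  coords <- QR_ALIGN[[version]]
  for (rc in coords) for (cc in coords) {
    r1 <- rc + 1L; c1 <- cc + 1L
    # skip the three corners occupied by finder patterns
    if (fun[r1, c1] && !(r1 == 7L || c1 == 7L)) next
    if ((rc <= 7 && cc <= 7) || (rc <= 7 && cc >= n - 8L) ||
        (rc >= n - 8L && cc <= 7)) next
    for (i in -2:2) for (j in -2:2) {
      v <- as.integer(max(abs(i), abs(j)) != 1L)
      base[r1 + i, c1 + j] <- v
      fun[r1 + i, c1 + j] <- TRUE
    }
  }
  # dark module
  base[n - 7L, 9L] <- 1L
  fun[n - 7L, 9L] <- TRUE
  # reserve format information areas
  for (p in format_positions(n)) fun[p[1L], p[2L]] <- TRUE
  # reserve version information areas
  if (version >= 7L) {
    fun[1:6, (n - 10L):(n - 8L)] <- TRUE
    fun[(n - 10L):(n - 8L), 1:6] <- TRUE
  }

  # placement order: column pairs right to left, skipping the timing column
  ord <- matrix(0L, sum(!fun), 2L)
  k <- 0L
  col <- n
  upward <- TRUE
  while (col > 0L) {
    if (col == 7L) col <- col - 1L # timing column is skipped entirely
    rows <- if (upward) n:1 else 1:n
    for (r in rows) for (c in c(col, col - 1L)) {
      if (c < 1L || fun[r, c]) next
      k <- k + 1L
      ord[k, ] <- c(r, c)
    }
    upward <- !upward
    col <- col - 2L
  }
  g <- list(fun = fun, base = base, order = ord, n = n)
  qr_env$geom[[key]] <- g
  g
}

# the two 15-bit format information copies; list of c(row, col) (1-indexed)
# for bits 0 (LSB) .. 14, first copy then second copy
format_positions <- function(n) {
  copy1 <- list(
    c(9, 1), c(9, 2), c(9, 3), c(9, 4), c(9, 5), c(9, 6), c(9, 8), c(9, 9),
    c(8, 9), c(6, 9), c(5, 9), c(4, 9), c(3, 9), c(2, 9), c(1, 9))
  copy2 <- c(
    lapply(0:6, function(i) c(n - i, 9)),
    lapply(0:7, function(i) c(9, n - 7 + i)))
  c(copy1, copy2)
}

bch_format <- function(ec_level, mask) {
  ec_bits <- c(L = 1L, M = 0L, Q = 3L, H = 2L)[[ec_level]]
  data5 <- ec_bits * 8L + mask
  v <- bitwShiftL(data5, 10L)
  for (i in 14:10)
    if (bitwAnd(v, bitwShiftL(1L, i)) != 0L)
      v <- bitwXor(v, bitwShiftL(0x537L, i - 10L))
  bitwXor(bitwOr(bitwShiftL(data5, 10L), v), 0x5412L)
}

bch_version <- function(version) {
  v <- bitwShiftL(version, 12L)
  for (i in 17:12)
    if (bitwAnd(v, bitwShiftL(1L, i)) != 0L)
      v <- bitwXor(v, bitwShiftL(0x1F25L, i - 12L))
  bitwOr(bitwShiftL(version, 12L), v)
}

mask_matrix <- function(n, mask) {
  i <- matrix(0:(n - 1L), n, n)        # row index, 0-based
  j <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  switch(as.character(mask),
    "0" = (i + j) %% 2L == 0L,
    "1" = i %% 2L == 0L,
    "2" = j %% 3L == 0L,
    "3" = (i + j) %% 3L == 0L,
    "4" = (i %/% 2L + j %/% 3L) %% 2L == 0L,
    "5" = (i * j) %% 2L + (i * j) %% 3L == 0L,
    "6" = ((i * j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    "7" = ((i + j) %% 2L + (i * j) %% 3L) %% 2L == 0L,
    stop_range("mask must be 0-7"))
}

# total codewords available in a version, derived purely from geometry —
# the independent check on the block table
qr_total_codewords <- function(version) {
  nrow(qr_geometry(version)$order) %/% 8L
}

# ---- encoding --------------------------------------------------------------

bits_msb <- function(value, width) {
  as.integer(bitwAnd(bitwShiftR(rep(as.integer(value), width),
                                (width - 1L):0L), 1L))
}

qr_encode_matrix <- function(payload, version, ec_level = "L", mask = 0L) {
  stopifnot(is.raw(payload))
  if (ec_level != "L")
    qrstab_error("qrstab_unsupported_error",
                 "symbol rendering is implemented for EC level L")
  cap <- QR_CAPACITY[version, ec_level]
  if (length(payload) > cap)
    stop_capacity(sprintf("payload of %d bytes exceeds version %d-%s capacity %d",
                          length(payload), version, ec_level, cap))
  blk <- QR_BLOCKS_L[version, ]
  n_data <- blk[["g1n"]] * blk[["g1d"]] + blk[["g2n"]] * blk[["g2d"]]
  len_bits <- if (version <= 9L) 8L else 16L

  bits <- c(bits_msb(4L, 4L),                     # byte mode indicator
            bits_msb(length(payload), len_bits),
            unlist(lapply(as.integer(payload), bits_msb, width = 8L)))
  bits <- c(bits, integer(min(4L, n_data * 8L - length(bits)))) # terminator
  if (length(bits) %% 8L != 0L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  cw <- integer(n_data)
  nb <- length(bits) %/% 8L
  if (nb > 0L)
    cw[seq_len(nb)] <- as.integer(colSums(matrix(bits, 8L) * 2L^(7:0)))
  if (n_data > nb)
    cw[(nb + 1L):n_data] <- rep(c(0xECL, 0x11L), length.out = n_data - nb)

  # split into blocks, compute RS parity, interleave
  sizes <- c(rep(blk[["g1d"]], blk[["g1n"]]), rep(blk[["g2d"]], blk[["g2n"]]))
  blocks <- split(cw, rep(seq_along(sizes), sizes))
  ecc <- lapply(blocks, rs_encode_block, n_ec = blk[["ec"]])
  maxd <- max(sizes)
  inter <- integer(0)
  for (i in seq_len(maxd))
    for (b in blocks) if (length(b) >= i) inter <- c(inter, b[i])
  for (i in seq_len(blk[["ec"]]))
    for (e in ecc) inter <- c(inter, e[i])

  g <- qr_geometry(version)
  data_bits <- unlist(lapply(inter, bits_msb, width = 8L))
  data_bits <- c(data_bits, integer(nrow(g$order) - length(data_bits)))

  mat <- g$base
  mat[g$order] <- data_bits
  mk <- mask_matrix(g$n, mask) & !g$fun
  mat[mk] <- 1L - mat[mk]

  fmt <- bch_format(ec_level, mask)
  fp <- format_positions(g$n)
  fbits <- bits_msb(fmt, 15L)[15:1] # index by bit number 0..14
  for (b in 0:14) {
    mat[fp[[b + 1L]][1L], fp[[b + 1L]][2L]] <- fbits[b + 1L]
    mat[fp[[b + 16L]][1L], fp[[b + 16L]][2L]] <- fbits[b + 1L]
  }
  if (version >= 7L) {
    vbits <- bits_msb(bch_version(version), 18L)[18:1]
    for (b in 0:17) {
      r <- g$n - 10L + b %% 3L
      c <- b %/% 3L + 1L
      mat[r, c] <- vbits[b + 1L]   # bottom-left copy
      mat[c, r] <- vbits[b + 1L]   # top-right copy (transposed)
    }
  }
  mat
}

# ---- decoding --------------------------------------------------------------

qr_decode_matrix <- function(mat) {
  n <- nrow(mat)
  version <- (n - 17L) %/% 4L
  if (n != ncol(mat) || version < 1L || version > 40L || (n - 17L) %% 4L != 0L)
    qrstab_error("qrstab_scan_error", "matrix is not a QR symbol size")
  g <- qr_geometry(version)

  fp <- format_positions(n)
  read_copy <- function(offset) {
    bits <- vapply(0:14, function(b)
      as.integer(mat[fp[[b + offset]][1L], fp[[b + offset]][2L]]), integer(1))
    sum(bits * 2L^(0:14))
  }
  candidates <- expand.grid(ec = c("L", "M", "Q", "H"), mask = 0:7,
                            stringsAsFactors = FALSE)
  fmt_tab <- mapply(function(e, m) bch_format(e, m), candidates$ec, candidates$mask)
  hit <- match(read_copy(1L), fmt_tab)
  if (is.na(hit)) hit <- match(read_copy(16L), fmt_tab)
  if (is.na(hit))
    qrstab_error("qrstab_scan_error", "format information unreadable")
  ec_level <- candidates$ec[hit]
  mask <- candidates$mask[hit]
  if (ec_level != "L")
    qrstab_error("qrstab_scan_error",
                 sprintf("EC level %s symbols are outside this decoder's support",
                         ec_level))

  mk <- mask_matrix(n, mask) & !g$fun
  um <- mat
  um[mk] <- 1L - um[mk]
  bits <- um[g$order]
  ncw <- length(bits) %/% 8L
  cw <- as.integer(colSums(matrix(bits[seq_len(ncw * 8L)], 8L) * 2L^(7:0)))

  blk <- QR_BLOCKS_L[version, ]
  sizes <- c(rep(blk[["g1d"]], blk[["g1n"]]), rep(blk[["g2d"]], blk[["g2n"]]))
  nblk <- length(sizes)
  data_cw <- vector("list", nblk)
  pos <- 1L
  for (i in seq_len(max(sizes)))
    for (b in seq_len(nblk))
      if (sizes[b] >= i) {
        data_cw[[b]] <- c(data_cw[[b]], cw[pos])
        pos <- pos + 1L
      }
  ecc_cw <- vector("list", nblk)
  for (i in seq_len(blk[["ec"]]))
    for (b in seq_len(nblk)) {
      ecc_cw[[b]] <- c(ecc_cw[[b]], cw[pos])
      pos <- pos + 1L
    }
  for (b in seq_len(nblk))
    if (!rs_syndromes_zero(c(data_cw[[b]], ecc_cw[[b]]), blk[["ec"]]))
      qrstab_error("qrstab_scan_error",
                   sprintf("Reed-Solomon check failed in block %d", b))

  stream <- unlist(data_cw)
  sbits <- unlist(lapply(stream, bits_msb, width = 8L))
  mode <- sum(sbits[1:4] * 2L^(3:0))
  if (mode != 4L)
    qrstab_error("qrstab_scan_error",
                 sprintf("unsupported data mode %d (byte mode expected)", mode))
  len_bits <- if (version <= 9L) 8L else 16L
  len <- sum(sbits[5:(4L + len_bits)] * 2L^((len_bits - 1L):0L))
  need <- 4L + len_bits + 8L * len
  if (need > length(sbits))
    qrstab_error("qrstab_scan_error", "declared length exceeds data stream")
  if (len == 0L) return(raw(0))
  payload_bits <- sbits[(4L + len_bits + 1L):need]
  as.raw(colSums(matrix(payload_bits, 8L) * 2L^(7:0)))
}
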