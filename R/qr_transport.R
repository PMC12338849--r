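#' QR transport configuration
#'
#' Bundles the symbol and print parameters of the transport: QR version 25
#' at error-correction level L (1273-byte symbols), 4x4-pixel modules, a
#' 4-module quiet zone, a 200-dpi print assumption and a 20% size redundancy
#' reserve for printer variation.
#'
#' @param version QR version 1-40 (default 25).
#' @param ec_level error-correction level; `"L"`, `"M"`, `"Q"` or `"H"`.
#' @param module_px rendered pixels per module.
#' @param dpi assumed printer resolution (dots per inch), advisory metadata
#'   for the physical-size arithmetic.
#' @param quiet_zone quiet-zone width in modules on each side.
#' @param redundancy fractional print-size reserve.
#' @return A `qrstab_qrconfig` list.
#' @export
qr_config <- function(version = 25L, ec_level = "L", module_px = 4L,
                      dpi = 200L, quiet_zone = 4L, redundancy = 0.20) {
  version <- assert_count(version, "version", 1L, 40L)
  ec_level <- match.arg(ec_level, c("L", "M", "Q", "H"))
  structure(
    list(version = version, ec_level = ec_level,
         module_px = assert_count(module_px, "module_px", 1L),
         dpi = assert_count(dpi, "dpi", 1L),
         quiet_zone = assert_count(quiet_zone, "quiet_zone", 0L),
         redundancy = redundancy),
    class = "qrstab_qrconfig")
}

#' QR symbol arithmetic: module count, byte capacity, printed size
#'
#' `qr_modules()` gives the symbol side length in modules, `17 + 4 x
#' version` (117 for version 25, 177 for version 40). `qr_capacity()` looks
#' up the byte-mode data capacity from the QR code specification tables —
#' 1273 bytes for version 25 at level L. `print_edge_inches()` computes the
#' printed edge `(modules + 2 x quiet_zone) x module_px / dpi`, optionally
#' inflated by the configured redundancy reserve: version 25 under the
#' defaults is 2.5 in (6.35 cm) theoretical and 3.0 in (7.62 cm) as
#' designed with the 20% reserve.
#'
#' @param version QR version 1-40.
#' @return `qr_modules()`: integer; `qr_capacity()`: integer bytes.
#' @export
#' @examples
#' qr_modules(25)        # 117
#' qr_capacity(25, "L")  # 1273
qr_modules <- function(version) {
  version <- assert_count(version, "version", 1L, 40L)
  17L + 4L * version
}

#' @rdname qr_modules
#' @param ec_level error-correction level `"L"`, `"M"`, `"Q"` or `"H"`.
#' @export
qr_capacity <- function(version, ec_level = "L") {
  version <- assert_count(version, "version", 1L, 40L)
  ec_level <- match.arg(ec_level, c("L", "M", "Q", "H"))
  as.integer(QR_CAPACITY[version, ec_level])
}

#' @rdname qr_modules
#' @param cfg a [qr_config()].
#' @param include_redundancy apply the configured fractional size reserve.
#' @return `print_edge_inches()`: named list with `inches` and `cm`.
#' @export
print_edge_inches <- function(cfg = qr_config(), include_redundancy = FALSE) {
  stopifnot(inherits(cfg, "qrstab_qrconfig"))
  edge <- (qr_modules(cfg$version) + 2L * cfg$quiet_zone) * cfg$module_px / cfg$dpi
  if (include_redundancy) edge <- edge * (1 + cfg$redundancy)
  list(inches = edge, cm = edge * 2.54)
}

#' Split an encrypted message body into QR packets
#'
#' Slices the ciphertext into `compute_count()` chunks of `capacity - 6`
#' bytes (the last chunk takes the remainder) and frames each with a header
#' whose fingerprint authenticates that chunk for `identity_id`. All headers
#' share version, transaction and count and differ only in seq and
#' fingerprint.
#'
#' @param cipher raw vector, the full encrypted body.
#' @param cfg a [qr_config()] fixing the symbol capacity.
#' @param version protocol version byte.
#' @param transaction 16-bit transaction id (see [encode_transaction()]).
#' @param identity_id recipient identifier for the per-packet fingerprint.
#' @param fingerprint_len tag length in bytes (protocol v1: 2).
#' @return List of `qrstab_packet` objects (header + body chunk).
#' @export
split_body <- function(cipher, cfg, version, transaction, identity_id,
                       fingerprint_len = 2L) {
  stopifnot(is.raw(cipher), inherits(cfg, "qrstab_qrconfig"))
  capacity <- qr_capacity(cfg$version, cfg$ec_level)
  count <- compute_count(length(cipher), capacity, 6L)
  chunk_len <- capacity - 6L
  lapply(seq_len(count) - 1L, function(s) {
    from <- s * chunk_len + 1L
    to <- min((s + 1L) * chunk_len, length(cipher))
    body <- cipher[from:to]
    h <- message_header(
      version = version,
      fingerprint = fingerprint(body, identity_id, fingerprint_len),
      transaction = transaction, count = count, seq = s)
    structure(list(header = h, body = body), class = "qrstab_packet")
  })
}

#' Serialize / parse one packet's wire bytes
#'
#' The raw packet carried in a QR symbol is `pack_header(header) || body`.
#'
#' @param packet a `qrstab_packet`.
#' @return `packet_bytes()`: raw vector; `parse_packet()`: a `qrstab_packet`.
#' @export
packet_bytes <- function(packet) {
  stopifnot(inherits(packet, "qrstab_packet"))
  c(pack_header(packet$header), packet$body)
}

#' @rdname packet_bytes
#' @param raw raw vector of at least 6 bytes.
#' @export
parse_packet <- function(raw) {
  h <- unpack_header(raw)
  structure(list(header = h,
                 body = if (length(raw) > 6L) raw[-(1:6)] else raw(0)),
            class = "qrstab_packet")
}

#' Render a packet as a QR symbol image / read a QR image back to bytes
#'
#' `render_qr()` encodes the packet's wire bytes into a byte-mode QR matrix
#' and rasterises it at `module_px` pixels per module with the configured
#' quiet zone, returning a grayscale image matrix (0 = dark) of class
#' `qrstab_qr_image` ready for [png::writePNG()] via [write_qr_png()].
#' `read_qr()` accepts such a matrix, any grayscale/RGB array, or a PNG file
#' path, and returns the decoded payload bytes; an image that does not
#' contain a well-formed symbol raises a scan error.
#'
#' @param packet a `qrstab_packet` (or raw payload bytes).
#' @param cfg a [qr_config()].
#' @return `render_qr()`: numeric matrix in `[0, 1]`; `read_qr()`: raw
#'   payload.
#' @export
render_qr <- function(packet, cfg = qr_config()) {
  payload <- if (is.raw(packet)) packet else packet_bytes(packet)
  mat <- qr_encode_matrix(payload, cfg$version, cfg$ec_level)
  px <- cfg$module_px
  img <- 1 - mat[rep(seq_len(nrow(mat)), each = px),
                 rep(seq_len(ncol(mat)), each = px)]
  qz <- cfg$quiet_zone * px
  full <- matrix(1, nrow(img) + 2L * qz, ncol(img) + 2L * qz)
  full[qz + seq_len(nrow(img)), qz + seq_len(ncol(img))] <- img
  structure(full, class = c("qrstab_qr_image", "matrix"),
            version = cfg$version, module_px = px)
}

#' @rdname render_qr
#' @param img image matrix/array, `qrstab_qr_image`, or PNG path.
#' @export
read_qr <- function(img) {
  if (is.character(img)) img <- png::readPNG(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    img <- if (nc >= 3L) (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3 else img[, , 1L]
  }
  img <- unclass(img)
  dark <- img < 0.5
  rows <- which(rowSums(dark) > 0L)
  cols <- which(colSums(dark) > 0L)
  if (length(rows) == 0L)
    qrstab_error("qrstab_scan_error", "no symbol found in image")
  sub <- dark[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
  h <- nrow(sub); w <- ncol(sub)
  if (abs(h - w) > max(2L, h %/% 50L))
    qrstab_error("qrstab_scan_error", "detected region is not square")
  for (version in 1:40) {
    m <- 17L + 4L * version
    px <- h / m
    if (px < 1 || abs(px - round(px)) > 1e-9) next
    px <- as.integer(round(px))
    centers <- as.integer((seq_len(m) - 0.5) * px + 0.5)
    mat <- matrix(as.integer(sub[centers, centers]), m, m)
    if (!finder_ok(mat)) next
    return(qr_decode_matrix(mat))
  }
  qrstab_error("qrstab_scan_error", "no readable QR symbol in image")
}

finder_ok <- function(mat) {
  eye <- function(r, c) {
    blk <- mat[r:(r + 6L), c:(c + 6L)]
    ref <- qr_geometry(1L)$base[1:7, 1:7]
    identical(blk, ref)
  }
  n <- nrow(mat)
  eye(1L, 1L) && eye(1L, n - 6L) && eye(n - 6L, 1L)
}

#' @rdname render_qr
#' @param path output PNG path.
#' @export
write_qr_png <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' @export
print.qrstab_packet <- function(x, ...) {
  cat(sprintf("<qrstab_packet> %s, body %d bytes\n", format(x$header),
              length(x$body)))
  invisible(x)
}
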