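#' Message header for one QR packet
#'
#' Every QR symbol in a transmission carries a fixed 6-byte (48-bit) header
#' followed by one chunk of the encrypted message body. The header holds five
#' bit-packed fields: an 8-bit protocol version, a 16-bit truncated
#' authentication fingerprint over the packet body and the recipient's
#' identifier, a 16-bit transaction identifier (the day offset of the
#' admission date from a configured epoch), a 4-bit packet count and a 4-bit
#' sequence number starting at 0.
#'
#' @param version integer 0-255, protocol version byte.
#' @param fingerprint 2-byte raw vector (or integer 0-65535): truncated
#'   digest of `body || identity`.
#' @param transaction integer 0-65535, day offset of the admission date from
#'   the profile's tag epoch.
#' @param count integer 1-15, number of packets the message is split into.
#' @param seq integer in `[0, count - 1]`, position of this packet.
#' @return An object of class `qrstab_header`.
#' @seealso [pack_header()], [unpack_header()], [encode_transaction()]
#' @export
#' @examples
#' h <- message_header(1, as.raw(c(0xBE, 0xEF)), 745, count = 2, seq = 1)
#' pack_header(h)
message_header <- function(version, fingerprint, transaction, count, seq = 0L) {
  version <- assert_count(version, "version", 0L, 255L)
  if (is.numeric(fingerprint)) {
    fp <- assert_count(fingerprint, "fingerprint", 0L, 65535L)
    fingerprint <- int_to_raw_be(fp, 2L)
  }
  if (!is.raw(fingerprint) || length(fingerprint) != 2L)
    stop_range("fingerprint must be 2 bytes")
  transaction <- assert_count(transaction, "transaction", 0L, 65535L)
  count <- assert_count(count, "count", 1L, 15L)
  seq <- assert_count(seq, "seq", 0L, 14L)
  if (seq >= count) stop_range("seq must be strictly smaller than count")
  structure(
    list(version = version, fingerprint = fingerprint,
         transaction = transaction, count = count, seq = seq),
    class = "qrstab_header"
  )
}

#' Pack a message header into its 6-byte wire form
#'
#' Bit layout, MSB first: version (8) || fingerprint (16) || transaction (16)
#' || count (4) || seq (4). Multi-byte integers are big-endian; the final
#' byte carries count in the high nibble and seq in the low nibble.
#'
#' @param h a `qrstab_header` from [message_header()].
#' @return A raw vector of exactly 6 bytes.
#' @export
pack_header <- function(h) {
  stopifnot(inherits(h, "qrstab_header"))
  c(int_to_raw_be(h$version, 1L),
    h$fingerprint,
    int_to_raw_be(h$transaction, 2L),
    as.raw(h$count * 16L + h$seq))
}

#' Unpack the first 6 bytes of a packet into a message header
#'
#' Inverse of [pack_header()]; reads only the first 6 bytes of `raw`.
#' A count nibble of 0 is reserved and rejected as a framing error, as is
#' input shorter than 6 bytes or a seq not smaller than count.
#'
#' @param raw raw vector of at least 6 bytes.
#' @return A `qrstab_header`.
#' @export
unpack_header <- function(raw) {
  if (!is.raw(raw) || length(raw) < 6L)
    stop_framing("header requires at least 6 bytes")
  last <- as.integer(raw[6L])
  count <- last %/% 16L
  seq <- last %% 16L
  if (count == 0L) stop_framing("count nibble 0 is reserved/invalid")
  if (seq >= count) stop_framing("seq nibble not smaller than count")
  message_header(
    version = as.integer(raw[1L]),
    fingerprint = raw[2:3],
    transaction = raw_to_int_be(raw[4:5]),
    count = count, seq = seq
  )
}

#' Encode an admission date as a 16-bit transaction identifier
#'
#' The transaction id groups the packets of one transmission. It is the
#' whole-day offset of the patient's admission date from a predefined tag
#' epoch shared by encoder and decoder (default "2020-01-01"), stored as an
#' unsigned big-endian 16-bit value in the header.
#'
#' @param adm_date admission date (`Date` or "YYYY-MM-DD" string).
#' @param tag_date tag epoch (`Date` or string); must not be after `adm_date`.
#' @return Integer in 0..65535.
#' @export
#' @examples
#' encode_transaction("2022-01-16", "2020-01-01") # 746 (2020 is a leap year)
encode_transaction <- function(adm_date, tag_date = "2020-01-01") {
  adm <- as.Date(adm_date)
  tag <- as.Date(tag_date)
  if (is.na(adm) || is.na(tag)) stop_range("invalid date")
  off <- as.integer(adm - tag)
  if (off < 0L) stop_range("admission date is before the tag epoch")
  if (off > 65535L) stop_range("day offset exceeds the 16-bit transaction range")
  off
}

#' Number of QR packets needed for a message body
#'
#' `ceiling(body_len / (qr_capacity - header_len))`: each symbol carries the
#' fixed-size header plus one chunk of the encrypted body. The 4-bit count
#' field caps a transmission at 15 packets.
#'
#' @param body_len total encrypted body length in bytes (>= 1).
#' @param qr_capacity byte capacity of one QR symbol.
#' @param header_len header length in bytes (6 for protocol version 1).
#' @return Integer packet count in 1..15.
#' @export
#' @examples
#' compute_count(1267, 1273) # 1: exactly one full payload
#' compute_count(1268, 1273) # 2: one byte over
compute_count <- function(body_len, qr_capacity, header_len = 6L) {
  body_len <- assert_count(body_len, "body_len", 0L)
  if (body_len == 0L) qrstab_error("qrstab_empty_error", "empty message body")
  qr_capacity <- assert_count(qr_capacity, "qr_capacity", header_len + 1L)
  n <- ceiling(body_len / (qr_capacity - header_len))
  if (n > 15L)
    stop_capacity(sprintf(
      "body of %d bytes needs %d packets; the 4-bit count field allows at most 15",
      body_len, n))
  as.integer(n)
}

#' @export
print.qrstab_header <- function(x, ...) {
  cat(sprintf(
    "<qrstab_header> v%d fp=%s transaction=%d count=%d seq=%d\n",
    x$version, raw_to_hex(x$fingerprint), x$transaction, x$count, x$seq))
  invisible(x)
}

#' @export
format.qrstab_header <- function(x, ...) {
  sprintf("v%d tx=%d %d/%d", x$version, x$transaction, x$seq + 1L, x$count)
}
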