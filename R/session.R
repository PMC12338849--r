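#' Encode a health record into authenticated QR packets
#'
#' Runs the full encoder pipeline in order: tokenize free-text fields,
#' serialize against the schema, deflate-compress, ChaCha20-encrypt under a
#' nonce derived from (version, transaction, count), split into packets, and
#' stamp each packet header with the truncated BLAKE3 fingerprint of its
#' ciphertext chunk and the recipient identity.
#'
#' @param rec a record validating against the profile schema.
#' @param identity_id recipient identifier; the decoder must log in with the
#'   same string for authentication to pass.
#' @param profile a [codec_profile()].
#' @param cfg QR transport configuration (defaults to the profile's).
#' @param render also rasterise each packet into a QR image matrix.
#' @return A `qrstab_encoding`: `packets` (list of `qrstab_packet`),
#'   `packet_bytes` (list of raw wire payloads), `images` (if `render`),
#'   `transaction`, `count` and `cipher_len`.
#' @export
#' @seealso [decode_session()], [submit_scan()]
encode_record <- function(rec, identity_id, profile, cfg = profile$qr,
                          render = TRUE) {
  stopifnot(inherits(profile, "qrstab_profile"))
  validate_record(rec, profile$schema)
  serialized <- serialize_record(rec, profile$schema, profile$tokenizer,
                                 epoch = profile$tag_epoch)
  compressed <- gzip_compress(serialized)
  transaction <- encode_transaction(rec$base$admissionDate, profile$tag_epoch)
  capacity <- qr_capacity(cfg$version, cfg$ec_level)
  count <- compute_count(length(compressed), capacity, 6L)
  nonce <- derive_nonce(profile, profile$version, transaction, count)
  cipher <- chacha20_encrypt(compressed, profile$secret, nonce)
  packets <- split_body(cipher, cfg, profile$version, transaction,
                        identity_id, profile$fingerprint_len)
  structure(
    list(packets = packets,
         packet_bytes = lapply(packets, packet_bytes),
         images = if (render) lapply(packets, render_qr, cfg = cfg),
         transaction = transaction, count = count,
         cipher_len = length(cipher)),
    class = "qrstab_encoding")
}

#' Multiversion codec registry
#'
#' The decoder dispatches each scanned packet on its version byte to the
#' matching codec profile, so one session can accept transmissions from
#' several encoders (e.g. different data centres or historical protocol
#' versions).
#'
#' @param ... zero or more `qrstab_profile` objects.
#' @return A `qrstab_registry` (named list keyed by version byte).
#' @export
profile_registry <- function(...) {
  reg <- structure(list(), class = "qrstab_registry")
  for (p in list(...)) reg <- register_profile(reg, p)
  reg
}

#' @rdname profile_registry
#' @param registry a `qrstab_registry`.
#' @param profile a `qrstab_profile` whose version byte is not yet registered.
#' @export
register_profile <- function(registry, profile) {
  stopifnot(inherits(registry, "qrstab_registry"),
            inherits(profile, "qrstab_profile"))
  key <- as.character(profile$version)
  if (!is.null(registry[[key]]))
    qrstab_error("qrstab_registry_error",
                 sprintf("version %d already registered", profile$version))
  registry[[key]] <- profile
  registry
}

#' Decoder-side reassembly session
#'
#' Holds the logged-in identity, the registry of codec profiles, and one
#' reassembly buffer per (version, transaction) so interleaved transmissions
#' (even two admissions of the same patient) do not collide. Each
#' [submit_scan()] returns one of the six response status codes:
#'
#' * `finished` — all packets received; decoding complete, record returned.
#' * `waiting` — packet accepted; scan the remaining codes.
#' * `duplicated` — this packet was already scanned (byte-identical).
#' * `tag_error` — not a packet this program's registered codecs recognise.
#' * `auth_failed` — fingerprint mismatch for the logged-in identity.
#' * `exception` — any failure after authentication (tampering, corrupt
#'   stream, inconsistent counts).
#'
#' @param identity_id the logged-in user identifier used to recompute
#'   packet fingerprints.
#' @param registry a [profile_registry()].
#' @return A `qrstab_session` environment.
#' @export
decode_session <- function(identity_id, registry) {
  stopifnot(inherits(registry, "qrstab_registry"))
  s <- new.env(parent = emptyenv())
  s$identity <- as.character(identity_id)
  s$registry <- registry
  s$buffers <- list()
  s$history <- character(0)
  class(s) <- "qrstab_session"
  s
}

scan_result <- function(code, payload = NULL, transaction = NULL) {
  structure(list(code = code, payload = payload, transaction = transaction),
            class = "qrstab_scan_result")
}

#' Submit one scanned packet to a decode session
#'
#' Status precedence: framing/version problems report `tag_error` before
#' the fingerprint is checked (`auth_failed`), duplicates are only reported
#' for authenticated byte-identical repeats, and decryption, decompression
#' or deserialization failures after a complete set of packets report
#' `exception`. On completion the reassembled, decrypted and deserialized
#' record is returned in the result's `payload` and `finished` is emitted
#' exactly once per transaction.
#'
#' @param session a [decode_session()].
#' @param raw the scanned packet bytes (wire form: 6-byte header + body),
#'   e.g. from [read_qr()].
#' @return A `qrstab_scan_result` with fields `code`, `payload`,
#'   `transaction`.
#' @export
submit_scan <- function(session, raw) {
  stopifnot(inherits(session, "qrstab_session"))
  res <- submit_scan_impl(session, raw)
  session$history <- c(session$history, res$code)
  res
}

submit_scan_impl <- function(session, raw) {
  if (!is.raw(raw)) return(scan_result("tag_error"))
  h <- tryCatch(unpack_header(raw), qrstab_error = function(e) NULL)
  if (is.null(h)) return(scan_result("tag_error"))
  profile <- session$registry[[as.character(h$version)]]
  if (is.null(profile)) return(scan_result("tag_error"))
  body <- if (length(raw) > 6L) raw[-(1:6)] else raw(0)

  tag <- fingerprint(body, session$identity, profile$fingerprint_len)
  if (!identical(tag[1:2], h$fingerprint))
    return(scan_result("auth_failed", transaction = h$transaction))

  key <- sprintf("%d:%d", h$version, h$transaction)
  buf <- session$buffers[[key]]
  if (is.null(buf))
    buf <- list(count = h$count, chunks = vector("list", h$count),
                done = FALSE)
  if (buf$count != h$count)
    return(scan_result("exception", transaction = h$transaction))

  slot <- h$seq + 1L
  if (!is.null(buf$chunks[[slot]])) {
    if (identical(buf$chunks[[slot]], body))
      return(scan_result("duplicated", transaction = h$transaction))
    return(scan_result("exception", transaction = h$transaction))
  }
  buf$chunks[[slot]] <- body
  complete <- !any(vapply(buf$chunks, is.null, logical(1)))
  session$buffers[[key]] <- buf
  if (!complete)
    return(scan_result("waiting", transaction = h$transaction))

  rec <- tryCatch({
    cipher <- do.call(c, buf$chunks)
    nonce <- derive_nonce(profile, h$version, h$transaction, h$count)
    plain <- chacha20_decrypt(cipher, profile$secret, nonce)
    serialized <- gzip_decompress(plain)
    deserialize_record(serialized, profile$schema, profile$tokenizer,
                       epoch = profile$tag_epoch)
  }, error = function(e) e)
  if (inherits(rec, "error")) {
    session$buffers[[key]] <- NULL # allow a clean rescan of the transaction
    return(scan_result("exception", transaction = h$transaction))
  }
  buf$done <- TRUE
  session$buffers[[key]] <- buf
  scan_result("finished", payload = rec, transaction = h$transaction)
}

#' @export
print.qrstab_scan_result <- function(x, ...) {
  cat(sprintf("<qrstab_scan_result> %s%s\n", x$code,
              if (!is.null(x$transaction))
                sprintf(" (transaction %d)", x$transaction) else ""))
  invisible(x)
}

#' @export
print.qrstab_session <- function(x, ...) {
  cat(sprintf("<qrstab_session> identity '%s', %d buffer(s), %d scan(s)\n",
              x$identity, length(x$buffers), length(x$history)))
  invisible(x)
}

#' @export
print.qrstab_encoding <- function(x, ...) {
  cat(sprintf("<qrstab_encoding> transaction %d: %d packet(s), %d cipher bytes\n",
              x$transaction, x$count, x$cipher_len))
  invisible(x)
}
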