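#' Codec profile: the offline-synchronised trust material of one protocol version
#'
#' Encoder and decoder never exchange key, schema or tokenizer over the QR
#' channel; they synchronise this bundle out of band. A profile pins a
#' protocol version byte to a 256-bit shared secret, a record schema, a
#' trained tokenizer, the tag epoch used for transaction ids and dates, the
#' fingerprint length (2 bytes under version 1) and the QR transport
#' configuration.
#'
#' @param version protocol version byte, 0-255.
#' @param secret 32-byte raw key (or 64-character hex string).
#' @param schema record schema (default [ehr_schema()]).
#' @param tokenizer a trained [train_tokenizer()] model.
#' @param tag_epoch `Date` (or string): day zero for transactions and dates.
#' @param fingerprint_len authentication tag length in bytes, 1-64.
#' @param qr a [qr_config()].
#' @return A `qrstab_profile`.
#' @export
codec_profile <- function(version = 1L, secret, schema = ehr_schema(),
                          tokenizer = NULL, tag_epoch = "2020-01-01",
                          fingerprint_len = 2L, qr = qr_config()) {
  version <- assert_count(version, "version", 0L, 255L)
  if (is.character(secret)) secret <- hex_to_raw(secret)
  if (!is.raw(secret) || length(secret) != 32L)
    stop_range("secret must be exactly 32 bytes (256 bits)")
  fingerprint_len <- assert_count(fingerprint_len, "fingerprint_len", 1L, 64L)
  if (!is.null(tokenizer)) stopifnot(inherits(tokenizer, "qrstab_tokenizer"))
  structure(
    list(version = version, secret = secret, schema = schema,
         tokenizer = tokenizer, tag_epoch = as.Date(tag_epoch),
         fingerprint_len = fingerprint_len, qr = qr,
         schema_fp = schema_fingerprint(schema)),
    class = "qrstab_profile")
}

#' Persist / load a codec profile directory
#'
#' Writes `profile.json` (version, epoch, fingerprint length, QR config,
#' schema fingerprint), `schema.avsc`, `key.hex` and the tokenizer model
#' pair (`tokenizer.model` / `tokenizer.json`) into `dir`.
#'
#' @param profile a `qrstab_profile`.
#' @param dir directory path (created if missing).
#' @export
save_profile <- function(profile, dir) {
  stopifnot(inherits(profile, "qrstab_profile"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(version = profile$version,
               tag_epoch = format(profile$tag_epoch, "%Y-%m-%d"),
               fingerprint_len = profile$fingerprint_len,
               schema_fingerprint = profile$schema_fp,
               qr = unclass(profile$qr))
  jsonlite::write_json(meta, file.path(dir, "profile.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_avsc(profile$schema, file.path(dir, "schema.avsc"))
  writeLines(raw_to_hex(profile$secret), file.path(dir, "key.hex"))
  if (!is.null(profile$tokenizer))
    save_tokenizer(profile$tokenizer, file.path(dir, "tokenizer"))
  invisible(dir)
}

#' @rdname save_profile
#' @export
load_profile <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "profile.json"),
                              simplifyVector = TRUE)
  tok <- if (file.exists(file.path(dir, "tokenizer.model")))
    load_tokenizer(file.path(dir, "tokenizer")) else NULL
  profile <- codec_profile(
    version = meta$version,
    secret = readLines(file.path(dir, "key.hex"), warn = FALSE)[1L],
    schema = read_avsc(file.path(dir, "schema.avsc")),
    tokenizer = tok,
    tag_epoch = meta$tag_epoch,
    fingerprint_len = meta$fingerprint_len,
    qr = do.call(qr_config, meta$qr))
  if (!identical(profile$schema_fp, meta$schema_fingerprint))
    qrstab_error("qrstab_profile_error",
                 "schema fingerprint mismatch in profile directory")
  profile
}

#' @export
print.qrstab_profile <- function(x, ...) {
  cat(sprintf(
    "<qrstab_profile> v%d, schema %s, %s tokenizer, epoch %s, tag %d bytes, QR v%d-%s\n",
    x$version, x$schema_fp,
    if (is.null(x$tokenizer)) "no" else x$tokenizer$algorithm,
    format(x$tag_epoch), x$fingerprint_len, x$qr$version, x$qr$ec_level))
  invisible(x)
}
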