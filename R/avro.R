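#' Zig-zag / varint encoding of signed integers
#'
#' Signed integers are first zig-zag mapped to unsigned (0, -1, 1, -2 ->
#' 0, 1, 2, 3) and then written as a base-128 varint, low group first with
#' the high bit as a continuation flag — the integer wire format of Avro
#' binary encoding. For example the integer 11 maps to the zig-zag value 22
#' and the single octet `0x16`.
#'
#' @param n a single integer (magnitude below 2^52).
#' @return `zigzag_encode()`: a raw vector of 1-8 bytes.
#' @export
#' @examples
#' zigzag_encode(11)  # 0x16
#' zigzag_decode(as.raw(0x16))$value
zigzag_encode <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != trunc(n))
    stop_range("zigzag_encode expects a single integer")
  n <- as.numeric(n)
  u <- if (n >= 0) 2 * n else -2 * n - 1
  out <- raw(0)
  repeat {
    grp <- u %% 128
    u <- u %/% 128
    if (u > 0) {
      out <- c(out, as.raw(grp + 128))
    } else {
      out <- c(out, as.raw(grp))
      break
    }
  }
  out
}

#' @rdname zigzag_encode
#' @param bytes raw vector starting with a varint.
#' @param pos 1-based offset of the varint start.
#' @return `zigzag_decode()`: a list with `value` (numeric) and `consumed`
#'   (number of bytes read).
#' @export
zigzag_decode <- function(bytes, pos = 1L) {
  if (!is.raw(bytes) || pos > length(bytes))
    stop_framing("varint truncated: no bytes to read")
  u <- 0
  shift <- 1
  i <- pos
  repeat {
    if (i > length(bytes)) stop_framing("varint truncated mid-sequence")
    if (i - pos >= 10L) stop_framing("varint longer than 10 bytes")
    b <- as.integer(bytes[i])
    u <- u + (b %% 128L) * shift
    i <- i + 1L
    if (b < 128L) break
    shift <- shift * 128
  }
  v <- if (u %% 2 == 0) u / 2 else -(u + 1) / 2
  list(value = v, consumed = i - pos)
}

# ---- internal schema-driven binary codec (Avro wire rules) -----------------
#
# Schemas are nested R lists: primitives "null", "boolean", "int", "long",
# "string", "bytes"; list(type = "record", name=, fields = list(list(name=,
# type=))); list(type = "array", items=); list(type = "union", branches =
# list(...)). Leaf annotations interpreted by this codec:
#   tokenized = TRUE  : JSON-side string; wire-side packed 2-byte token ids
#                       when a tokenizer is supplied, else an Avro string.
#   decimal = k       : JSON-side numeric with k decimal places; wire-side
#                       scaled zig-zag varint int.
#   date = TRUE       : JSON-side "YYYY-MM-DD" string; wire-side zig-zag
#                       varint day offset from the codec epoch.
# The output stream carries no field names and no type tags (unions excepted,
# which write their branch index) — a reader without the schema cannot
# structurally parse it.

schema_type <- function(schema) {
  if (is.character(schema)) schema else schema$type
}

avro_encode_value <- function(value, schema, tok, epoch, path, parts) {
  ty <- schema_type(schema)
  emit <- function(r) parts$push(r)
  if (is.list(schema) && isTRUE(schema$tokenized) && !is.null(tok) && ty == "string") {
    if (!is.character(value) || length(value) != 1L)
      validation_error(path, "expected a string")
    packed <- pack_tokens(encode_text(tok, value))
    emit(zigzag_encode(length(packed)))
    emit(packed)
    return(invisible())
  }
  if (is.list(schema) && !is.null(schema$decimal) && ty %in% c("int", "long")) {
    if (!is.numeric(value) || length(value) != 1L || is.na(value))
      validation_error(path, "expected a number")
    emit(zigzag_encode(round(value * 10^schema$decimal)))
    return(invisible())
  }
  if (is.list(schema) && isTRUE(schema$date) && ty %in% c("int", "long")) {
    d <- suppressWarnings(as.Date(value))
    if (length(d) != 1L || is.na(d)) validation_error(path, "expected a YYYY-MM-DD date")
    emit(zigzag_encode(as.integer(d - epoch)))
    return(invisible())
  }
  switch(ty,
    "null" = {
      if (!is.null(value)) validation_error(path, "expected null")
    },
    "boolean" = {
      if (!is.logical(value) || length(value) != 1L || is.na(value))
        validation_error(path, "expected a boolean")
      emit(as.raw(as.integer(value)))
    },
    "int" = ,
    "long" = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
          value != trunc(value))
        validation_error(path, "expected an integer")
      emit(zigzag_encode(value))
    },
    "string" = {
      if (!is.character(value) || length(value) != 1L || is.na(value))
        validation_error(path, "expected a string")
      b <- charToRaw(enc2utf8(value))
      emit(zigzag_encode(length(b)))
      emit(b)
    },
    "bytes" = {
      if (!is.raw(value)) validation_error(path, "expected raw bytes")
      emit(zigzag_encode(length(value)))
      emit(value)
    },
    "record" = {
      if (!is.list(value)) validation_error(path, "expected a record object")
      for (f in schema$fields) {
        if (!f$name %in% names(value) &&
            !("null" %in% vapply(branches_of(f$type), schema_type, character(1))))
          validation_error(c(path, f$name), "missing required field")
        avro_encode_value(value[[f$name]], f$type, tok, epoch,
                          c(path, f$name), parts)
      }
    },
    "array" = {
      if (!is.list(value) && !is.null(value))
        validation_error(path, "expected an array (list)")
      n <- length(value)
      if (n > 0L) {
        emit(zigzag_encode(n))
        for (i in seq_len(n))
          avro_encode_value(value[[i]], schema$items, tok, epoch,
                            c(path, sprintf("[%d]", i)), parts)
      }
      emit(as.raw(0L)) # end-of-blocks marker
    },
    "union" = {
      idx <- union_branch_index(value, schema$branches)
      if (is.na(idx)) validation_error(path, "value matches no union branch")
      emit(zigzag_encode(idx - 1L))
      avro_encode_value(value, schema$branches[[idx]], tok, epoch, path, parts)
    },
    validation_error(path, sprintf("unknown schema type '%s'", ty))
  )
  invisible()
}

branches_of <- function(schema) {
  if (is.list(schema) && identical(schema$type, "union")) schema$branches
  else list(schema)
}

union_branch_index <- function(value, branches) {
  types <- vapply(branches, schema_type, character(1))
  if (is.null(value)) return(match("null", types))
  for (i in seq_along(branches)) {
    ty <- types[i]
    ok <- switch(ty,
      "null" = FALSE,
      "boolean" = is.logical(value),
      "int" = , "long" = is.numeric(value),
      "string" = is.character(value),
      "bytes" = is.raw(value),
      "record" = is.list(value),
      "array" = is.list(value),
      FALSE)
    if (ok) return(i)
  }
  NA_integer_
}

validation_error <- function(path, msg) {
  qrstab_error("qrstab_validation_error",
               sprintf("at %s: %s",
                       if (length(path)) paste(path, collapse = "/") else "<root>",
                       msg))
}

avro_decode_value <- function(cur, schema, tok, epoch, path) {
  ty <- schema_type(schema)
  read_varint <- function() {
    z <- zigzag_decode(cur$bytes, cur$pos)
    cur$pos <- cur$pos + z$consumed
    z$value
  }
  take <- function(n) {
    if (cur$pos + n - 1L > length(cur$bytes))
      qrstab_error("qrstab_deserialization_error",
                   sprintf("at %s: stream truncated", paste(path, collapse = "/")))
    out <- if (n == 0L) raw(0) else cur$bytes[cur$pos:(cur$pos + n - 1L)]
    cur$pos <- cur$pos + n
    out
  }
  if (is.list(schema) && isTRUE(schema$tokenized) && !is.null(tok) && ty == "string") {
    n <- read_varint()
    if (n < 0) qrstab_error("qrstab_deserialization_error", "negative byte length")
    return(decode_text(tok, unpack_tokens(take(n))))
  }
  if (is.list(schema) && !is.null(schema$decimal) && ty %in% c("int", "long")) {
    return(read_varint() / 10^schema$decimal)
  }
  if (is.list(schema) && isTRUE(schema$date) && ty %in% c("int", "long")) {
    return(format(epoch + read_varint(), "%Y-%m-%d"))
  }
  switch(ty,
    "null" = NULL,
    "boolean" = as.logical(as.integer(take(1L))),
    "int" = ,
    "long" = {
      v <- read_varint()
      if (abs(v) <= .Machine$integer.max) as.integer(v) else v
    },
    "string" = {
      n <- read_varint()
      if (n < 0) qrstab_error("qrstab_deserialization_error", "negative string length")
      s <- rawToChar(take(n))
      Encoding(s) <- "UTF-8"
      s
    },
    "bytes" = {
      n <- read_varint()
      if (n < 0) qrstab_error("qrstab_deserialization_error", "negative byte length")
      take(n)
    },
    "record" = {
      out <- vector("list", length(schema$fields))
      names(out) <- vapply(schema$fields, `[[`, character(1), "name")
      for (i in seq_along(schema$fields)) {
        f <- schema$fields[[i]]
        v <- avro_decode_value(cur, f$type, tok, epoch, c(path, f$name))
        out[i] <- list(v)
      }
      out
    },
    "array" = {
      out <- list()
      repeat {
        n <- read_varint()
        if (n == 0) break
        if (n < 0) { # block with byte-size prefix (written by other encoders)
          read_varint()
          n <- -n
        }
        for (i in seq_len(n))
          out[[length(out) + 1L]] <-
            avro_decode_value(cur, schema$items, tok, epoch,
                              c(path, sprintf("[%d]", length(out) + 1L)))
      }
      out
    },
    "union" = {
      idx <- read_varint() + 1
      if (idx < 1 || idx > length(schema$branches))
        qrstab_error("qrstab_deserialization_error",
                     sprintf("at %s: union branch %d out of range",
                             paste(path, collapse = "/"), idx))
      avro_decode_value(cur, schema$branches[[idx]], tok, epoch, path)
    },
    qrstab_error("qrstab_deserialization_error",
                 sprintf("unknown schema type '%s'", ty))
  )
}

#' Serialize a health record to schema-driven binary form
#'
#' Walks the record against the schema emitting Avro binary wire format:
#' zig-zag varints for integers, length-prefixed byte strings, block-encoded
#' arrays, and union branch indices. Field names and types are never written
#' — the reader must hold the identical schema, which is exactly why the
#' schema is part of the offline-synchronised codec profile rather than the
#' QR payload. When a tokenizer is supplied, schema fields marked as
#' tokenized free text are first converted to packed 2-byte token ids.
#'
#' @param rec a record (named list) matching `schema`.
#' @param schema a record schema, e.g. [ehr_schema()].
#' @param tok optional `qrstab_tokenizer`; `NULL` serializes text fields as
#'   plain strings.
#' @param epoch `Date` used as day-zero for date fields.
#' @return Raw vector.
#' @export
serialize_record <- function(rec, schema, tok = NULL,
                             epoch = as.Date("2020-01-01")) {
  buf <- new.env(parent = emptyenv())
  buf$items <- vector("list", 256L)
  buf$n <- 0L
  buf$push <- function(r) {
    if (length(r) == 0L) return(invisible())
    buf$n <- buf$n + 1L
    if (buf$n > length(buf$items))
      buf$items <- c(buf$items, vector("list", length(buf$items)))
    buf$items[[buf$n]] <- r
  }
  avro_encode_value(rec, schema, tok, epoch, character(0), buf)
  do.call(c, buf$items[seq_len(buf$n)])
}

#' @rdname serialize_record
#' @param raw raw vector produced by [serialize_record()] under the same
#'   schema (and tokenizer, if any).
#' @export
deserialize_record <- function(raw, schema, tok = NULL,
                               epoch = as.Date("2020-01-01")) {
  stopifnot(is.raw(raw))
  cur <- new.env(parent = emptyenv())
  cur$bytes <- raw
  cur$pos <- 1L
  out <- withCallingHandlers(
    avro_decode_value(cur, schema, tok, epoch, character(0)),
    qrstab_framing_error = function(e)
      qrstab_error("qrstab_deserialization_error", conditionMessage(e))
  )
  if (cur$pos != length(raw) + 1L)
    qrstab_error("qrstab_deserialization_error",
                 sprintf("%d trailing bytes after record",
                         length(raw) - cur$pos + 1L))
  out
}

#' Validate a record against a schema without serializing it
#'
#' @inheritParams serialize_record
#' @return `TRUE` invisibly; otherwise an error whose message names the
#'   offending field path.
#' @export
validate_record <- function(rec, schema) {
  sink <- new.env(parent = emptyenv())
  sink$push <- function(r) invisible()
  avro_encode_value(rec, schema, NULL, as.Date("2020-01-01"), character(0), sink)
  invisible(TRUE)
}
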