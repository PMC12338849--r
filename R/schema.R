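#' The seven-section deidentified health-record schema
#'
#' Defines the structured record carried by the protocol: a `base` section of
#' exactly 10 demographic/stay fields plus six repeated sections — surgical
#' history (`operate`), radiological examinations (`image`), laboratory
#' results (`lab`), risk assessments (`ass`), disease diagnoses (`disease`)
#' and discharge medication (`drug`). Every repeated section may be empty.
#' The record is a limited data set: it carries no direct patient identifier;
#' identity enters the protocol only through the authentication fingerprint.
#'
#' Free-text fields (department, surgery/exam/disease/drug/indicator/scale
#' names, imaging conclusions, risk factors, units, ranges, frequencies) are
#' marked as tokenized: with a tokenizer present they travel as packed
#' 2-byte token ids. Dates travel as day offsets from the codec epoch;
#' decimal measurements as scaled integers (1 or 2 decimal places), so
#' serialization round-trips are bit-exact.
#'
#' @return A record schema usable with [serialize_record()].
#' @export
ehr_schema <- function() {
  txt <- function(name) list(name = name, type = list(type = "string", tokenized = TRUE))
  str <- function(name) list(name = name, type = "string")
  int <- function(name) list(name = name, type = "int")
  dec <- function(name, k) list(name = name, type = list(type = "int", decimal = k))
  dat <- function(name) list(name = name, type = list(type = "int", date = TRUE))
  arr <- function(name, fields) list(
    name = name,
    type = list(type = "array",
                items = list(type = "record", name = paste0(name, "_item"),
                             fields = fields)))
  list(
    type = "record", name = "EHRRecord",
    fields = list(
      list(name = "base", type = list(
        type = "record", name = "base_rec",
        fields = list(
          int("age"), str("gender"), dec("height", 1L), dec("weight", 1L),
          dec("bmi", 1L), txt("department"), int("hospitalDays"),
          dat("admissionDate"), dat("dischargeDate"), str("admissionType")
        ))),
      arr("operate", list(txt("surgeryName"), dat("surgeryDate"))),
      arr("image", list(dat("examDate"), txt("examName"), txt("bodyPart"),
                        txt("conclusion"))),
      arr("lab", list(txt("indicatorName"), dec("value", 2L), txt("unit"),
                      str("riskFlag"), txt("normalRange"))),
      arr("ass", list(txt("scaleName"), str("riskLevel"), txt("riskFactors"))),
      arr("disease", list(txt("diseaseName"), txt("category"))),
      arr("drug", list(txt("drugName"), dec("dailyDose", 2L), txt("frequency")))
    )
  )
}

schema_to_avsc <- function(schema) {
  conv <- function(s) {
    if (is.character(s)) return(s)
    if (identical(s$type, "union")) return(lapply(s$branches, conv))
    if (identical(s$type, "record"))
      return(list(type = "record", name = s$name,
                  fields = lapply(s$fields, function(f)
                    list(name = f$name, type = conv(f$type)))))
    if (identical(s$type, "array"))
      return(list(type = "array", items = conv(s$items)))
    out <- list(type = s$type)
    if (isTRUE(s$tokenized)) out[["qrstab.tokenized"]] <- TRUE
    if (!is.null(s$decimal)) out[["qrstab.decimal"]] <- s$decimal
    if (isTRUE(s$date)) out[["qrstab.date"]] <- TRUE
    if (length(out) == 1L) out$type else out
  }
  conv(schema)
}

avsc_to_schema <- function(x) {
  conv <- function(s) {
    if (is.character(s) && length(s) == 1L) return(s)
    if (is.list(s) && is.null(names(s))) # JSON array = union
      return(list(type = "union", branches = lapply(s, conv)))
    ty <- s$type
    if (identical(ty, "record"))
      return(list(type = "record", name = s$name,
                  fields = lapply(s$fields, function(f)
                    list(name = f$name, type = conv(f$type)))))
    if (identical(ty, "array"))
      return(list(type = "array", items = conv(s$items)))
    out <- list(type = ty)
    if (isTRUE(s[["qrstab.tokenized"]])) out$tokenized <- TRUE
    if (!is.null(s[["qrstab.decimal"]])) out$decimal <- as.integer(s[["qrstab.decimal"]])
    if (isTRUE(s[["qrstab.date"]])) out$date <- TRUE
    if (length(out) == 1L) out$type else out
  }
  conv(x)
}

#' Read / write a schema as an Avro schema JSON (.avsc) document
#'
#' @param schema a record schema.
#' @param path file path.
#' @export
write_avsc <- function(schema, path) {
  jsonlite::write_json(schema_to_avsc(schema), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_avsc
#' @export
read_avsc <- function(path) {
  avsc_to_schema(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Short fingerprint of a schema definition
#'
#' BLAKE3 digest (first 8 bytes, hex) of the minified canonical schema JSON;
#' used to check out-of-band that writer and reader hold the same schema.
#'
#' @param schema a record schema.
#' @return A 16-character hex string.
#' @export
schema_fingerprint <- function(schema) {
  canon <- jsonlite::toJSON(schema_to_avsc(schema), auto_unbox = TRUE)
  raw_to_hex(blake3(charToRaw(canon), length = 8L))
}

#' Convert a record to/from minified JSON
#'
#' `record_to_json()` is the byte-size reference for compression ratios:
#' minified UTF-8 JSON with fields in schema order. `record_from_json()`
#' parses and canonicalises types against the schema (integers as R
#' integers, decimals as doubles), so that a JSON round-trip compares
#' `identical()` to the source record.
#'
#' @param rec a record (named list).
#' @param schema the record schema (used for field order/canonical types).
#' @return `record_to_json()`: a single JSON string; `record_json_bytes()`
#'   its UTF-8 size in bytes; `record_from_json()`: a record.
#' @export
record_to_json <- function(rec, schema = ehr_schema()) {
  rec <- canonicalize_record(rec, schema)
  as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' @rdname record_to_json
#' @export
record_json_bytes <- function(rec, schema = ehr_schema()) {
  length(charToRaw(enc2utf8(record_to_json(rec, schema))))
}

#' @rdname record_to_json
#' @param json a JSON string or file path.
#' @export
record_from_json <- function(json, schema = ehr_schema()) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  canonicalize_record(x, schema)
}

#' @rdname record_to_json
#' @param value a record (or sub-value during recursion).
#' @export
canonicalize_record <- function(value, schema) {
  ty <- schema_type(schema)
  if (is.list(schema)) {
    if (!is.null(schema$decimal) || isTRUE(schema$date)) {
      return(if (isTRUE(schema$date)) as.character(value) else as.numeric(value))
    }
  }
  switch(ty,
    "record" = {
      out <- vector("list", length(schema$fields))
      names(out) <- vapply(schema$fields, `[[`, character(1), "name")
      for (i in seq_along(schema$fields)) {
        f <- schema$fields[[i]]
        out[i] <- list(canonicalize_record(value[[f$name]], f$type))
      }
      out
    },
    "array" = lapply(if (is.null(value)) list() else value,
                     canonicalize_record, schema = schema$items),
    "union" = {
      if (is.null(value)) return(NULL)
      nn <- Filter(function(b) !identical(schema_type(b), "null"), schema$branches)
      canonicalize_record(value, nn[[1L]])
    },
    "int" = , "long" = as.integer(value),
    "boolean" = as.logical(value),
    "string" = {
      v <- enc2utf8(as.character(value))
      v
    },
    value
  )
}
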