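test_that("zig-zag varints match the bit-arithmetic oracle", {
  expect_identical(zigzag_encode(11), as.raw(0x16))
  expect_identical(zigzag_encode(0), as.raw(0x00))
  expect_identical(zigzag_encode(-1), as.raw(0x01))
  # independent oracle: (n << 1) XOR (n >> 31) on 32-bit integers (arithmetic
  # shift: all-ones for negative n), then LEB128
  oracle <- function(n) {
    u <- bitwXor(bitwShiftL(n, 1), if (n < 0) -1L else 0L)
    out <- raw(0)
    repeat {
      grp <- u %% 128
      u <- u %/% 128
      out <- c(out, as.raw(grp + 128 * (u > 0)))
      if (u == 0) return(out)
    }
  }
  for (n in seq(-10000L, 10000L, by = 7L)) {
    expect_identical(zigzag_encode(n), oracle(n))
    expect_identical(zigzag_decode(zigzag_encode(n))$value, as.numeric(n))
  }
  expect_error(zigzag_decode(raw(0)), class = "qrstab_framing_error")
  expect_error(zigzag_decode(as.raw(rep(0x80, 3))),
               class = "qrstab_framing_error")
})

test_that("an integer field of 11 serializes to the 0x16 octet in place", {
  schema <- ehr_schema()
  rec <- qa_record(3)
  rec$base$hospitalDays <- 11L
  rec2 <- rec
  rec2$base$hospitalDays <- 12L
  b1 <- serialize_record(rec, schema)
  b2 <- serialize_record(rec2, schema)
  diff_at <- which(b1 != b2)
  expect_length(diff_at, 1L)
  expect_identical(b1[diff_at], as.raw(0x16)) # 11 -> zig-zag 22 -> 0x16
  expect_identical(b2[diff_at], as.raw(0x18)) # 12 -> zig-zag 24 -> 0x18
})

test_that("records round-trip through serialization, with and without tokenizer", {
  schema <- ehr_schema()
  tok <- qa_bpe()
  empty <- canon(list(
    base = qa_record(1)$base, operate = list(), image = list(), lab = list(),
    ass = list(), disease = list(), drug = list()))
  expect_identical(deserialize_record(serialize_record(empty, schema), schema),
                   empty)
  for (rec in lapply(qa_records(60), canon)) {
    plain <- serialize_record(rec, schema)
    expect_identical(deserialize_record(plain, schema), rec)
    tokked <- serialize_record(rec, schema, tok)
    expect_identical(deserialize_record(tokked, schema, tok), rec)
  }
})

test_that("truncated or foreign-schema streams fail without crashing", {
  schema <- ehr_schema()
  rec <- canon(qa_record(8))
  bytes <- serialize_record(rec, schema)
  expect_error(deserialize_record(bytes[-length(bytes)], schema),
               class = "qrstab_deserialization_error")
  expect_error(deserialize_record(c(bytes, as.raw(1)), schema),
               class = "qrstab_deserialization_error")
  # a deliberately different schema: either a clean error or a (wrong)
  # structurally-valid record — never a crash
  other <- list(type = "record", name = "other", fields = list(
    list(name = "a", type = "string"),
    list(name = "b", type = list(type = "array", items = "long"))))
  out <- tryCatch(deserialize_record(bytes, other),
                  error = function(e) "error")
  expect_true(identical(out, "error") || is.list(out))
})

test_that("validation errors carry the offending field path", {
  schema <- ehr_schema()
  rec <- canon(qa_record(2))
  rec$base$age <- "not a number"
  err <- tryCatch(validate_record(rec, schema), error = function(e) e)
  expect_s3_class(err, "qrstab_validation_error")
  expect_match(conditionMessage(err), "base/age")
  rec2 <- canon(qa_record(2))
  rec2$lab[[1]]$value <- NULL
  expect_error(validate_record(rec2, schema),
               class = "qrstab_validation_error")
})

test_that("binary output hides structure: smaller than JSON, no field names", {
  schema <- ehr_schema()
  field_names <- c("indicatorName", "hospitalDays", "admissionDate",
                   "conclusion", "diseaseName", "normalRange")
  contains_bytes <- function(hay, needle) {
    nn <- length(needle)
    starts <- which(hay == needle[1])
    starts <- starts[starts <= length(hay) - nn + 1]
    any(vapply(starts, function(i) identical(hay[i:(i + nn - 1)], needle),
               logical(1)))
  }
  for (rec in lapply(qa_records(20), canon)) {
    ser <- serialize_record(rec, schema, qa_bpe())
    expect_lt(length(ser), record_json_bytes(rec, schema))
    for (fn in field_names)
      expect_false(contains_bytes(ser, charToRaw(fn)))
  }
})

test_that("schemas survive the .avsc round trip with the same fingerprint", {
  schema <- ehr_schema()
  path <- withr::local_tempfile(fileext = ".avsc")
  write_avsc(schema, path)
  back <- read_avsc(path)
  expect_identical(schema_fingerprint(back), schema_fingerprint(schema))
  rec <- canon(qa_record(4))
  expect_identical(deserialize_record(serialize_record(rec, back), back), rec)
})
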