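test_that("a single-packet transmission finishes on first scan", {
  prof <- qa_profile()
  reg <- profile_registry(prof)
  rec <- qa_record(11)
  enc <- encode_record(rec, "patient-001", prof, render = FALSE)
  ses <- decode_session("patient-001", reg)
  res <- submit_scan(ses, enc$packet_bytes[[1]])
  if (enc$count == 1L) {
    expect_identical(res$code, "finished")
    expect_identical(res$payload, canon(rec))
  }
})

test_that("the scan state machine walks waiting -> duplicated -> finished", {
  prof <- qa_profile()
  reg <- profile_registry(prof)
  rec <- qa_big_record(5)
  enc <- encode_record(rec, "patient-001", prof, render = FALSE)
  expect_gte(enc$count, 2L)
  ses <- decode_session("patient-001", reg)
  expect_identical(submit_scan(ses, enc$packet_bytes[[1]])$code, "waiting")
  expect_identical(submit_scan(ses, enc$packet_bytes[[1]])$code, "duplicated")
  res <- NULL
  for (pb in enc$packet_bytes[-1]) res <- submit_scan(ses, pb)
  expect_identical(res$code, "finished")
  expect_identical(res$payload, canon(rec))
  # finished is emitted exactly once; a re-scan afterwards is a duplicate
  expect_identical(submit_scan(ses, enc$packet_bytes[[1]])$code, "duplicated")
  expect_identical(sum(ses$history == "finished"), 1L)
})

test_that("completion is order-independent with an identical record", {
  prof <- qa_profile()
  reg <- profile_registry(prof)
  rec <- qa_big_record(6)
  enc <- encode_record(rec, "p", prof, render = FALSE)
  expect_gte(enc$count, 2L)
  expected <- canon(rec)
  set.seed(123)
  for (i in 1:5) {
    perm <- sample(enc$count)
    ses <- decode_session("p", reg)
    res <- NULL
    for (j in perm) res <- submit_scan(ses, enc$packet_bytes[[j]])
    expect_identical(res$code, "finished")
    expect_identical(res$payload, expected)
  }
})

test_that("authentication binds packets to the logged-in identity", {
  prof <- qa_profile()
  reg <- profile_registry(prof)
  enc <- encode_record(qa_record(12), "patient-001", prof, render = FALSE)
  ses <- decode_session("patient-002", reg)
  expect_identical(submit_scan(ses, enc$packet_bytes[[1]])$code, "auth_failed")
})

test_that("unknown framing and unregistered versions report tag_error", {
  prof <- qa_profile()
  reg <- profile_registry(prof)
  ses <- decode_session("p", reg)
  expect_identical(submit_scan(ses, as.raw(1:3))$code, "tag_error")
  expect_identical(submit_scan(ses, c(raw(5), as.raw(0x00)))$code, "tag_error")
  # valid frame, but version byte 9 has no registered codec
  enc <- encode_record(qa_record(13), "p", prof, render = FALSE)
  alien <- enc$packet_bytes[[1]]
  alien[1] <- as.raw(9)
  expect_identical(submit_scan(ses, alien)$code, "tag_error")
  # an empty registry rejects everything
  ses0 <- decode_session("p", profile_registry())
  expect_identical(submit_scan(ses0, enc$packet_bytes[[1]])$code, "tag_error")
})

test_that("post-authentication failures map to exception", {
  prof <- qa_profile()
  reg <- profile_registry(prof)
  # two different records sharing an admission date produce packets with the
  # same (version, transaction); colliding seq slots with different bodies
  # signal tampering
  r1 <- qa_big_record(41)
  r2 <- qa_big_record(42)
  r2$base$admissionDate <- r1$base$admissionDate
  e1 <- encode_record(r1, "p", prof, render = FALSE)
  e2 <- encode_record(r2, "p", prof, render = FALSE)
  expect_identical(e1$transaction, e2$transaction)
  if (e1$count == e2$count) {
    ses <- decode_session("p", reg)
    expect_identical(submit_scan(ses, e1$packet_bytes[[1]])$code, "waiting")
    expect_identical(submit_scan(ses, e2$packet_bytes[[1]])$code, "exception")
  }
  # count disagreement within one transaction
  r3 <- qa_record(43)
  r3$base$admissionDate <- r1$base$admissionDate
  e3 <- encode_record(r3, "p", prof, render = FALSE)
  if (e3$count != e1$count) {
    ses <- decode_session("p", reg)
    submit_scan(ses, e1$packet_bytes[[1]])
    expect_identical(submit_scan(ses, e3$packet_bytes[[1]])$code, "exception")
  }
})

test_that("a registry dispatches by version byte across profiles", {
  prof1 <- qa_profile()
  prof2 <- codec_profile(version = 2L, secret = random_secret(77),
                         tokenizer = qa_bpe())
  reg <- profile_registry(prof1, prof2)
  expect_error(register_profile(reg, prof1), class = "qrstab_registry_error")
  r1 <- qa_record(21)
  r2 <- qa_record(22)
  e1 <- encode_record(r1, "p", prof1, render = FALSE)
  e2 <- encode_record(r2, "p", prof2, render = FALSE)
  ses <- decode_session("p", reg)
  out <- list()
  for (pb in c(e1$packet_bytes, e2$packet_bytes))
    out[[length(out) + 1L]] <- submit_scan(ses, pb)
  finished <- Filter(function(r) r$code == "finished", out)
  expect_length(finished, 2L)
  got <- lapply(finished, `[[`, "payload")
  expect_true(identical(got[[1]], canon(r1)) || identical(got[[2]], canon(r1)))
  expect_true(identical(got[[1]], canon(r2)) || identical(got[[2]], canon(r2)))
})

test_that("packet bytes leak no plaintext field content", {
  prof <- qa_profile()
  rec <- qa_record(31)
  enc <- encode_record(rec, "p", prof, render = FALSE)
  all_bytes <- do.call(c, enc$packet_bytes)
  contains_bytes <- function(hay, needle) {
    nn <- length(needle)
    starts <- which(hay == needle[1])
    starts <- starts[starts <= length(hay) - nn + 1]
    any(vapply(starts, function(i) identical(hay[i:(i + nn - 1)], needle),
               logical(1)))
  }
  for (s in c(rec$base$department, rec$lab[[1]]$indicatorName,
              rec$disease[[1]]$diseaseName, "indicatorName"))
    expect_false(contains_bytes(all_bytes, charToRaw(enc2utf8(s))))
})

test_that("encoding renders one image per packet when asked", {
  prof <- qa_profile()
  enc <- encode_record(qa_record(15), "p", prof, render = TRUE)
  expect_length(enc$images, enc$count)
  expect_identical(read_qr(enc$images[[1]]), enc$packet_bytes[[1]])
})
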