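test_that("record generation is deterministic per seed", {
  gp <- qa_generator()
  expect_identical(generate_record(gp, 123), generate_record(gp, 123))
  expect_false(identical(generate_record(gp, 123), generate_record(gp, 124)))
  # batches derive consecutive seeds, so any record is reproducible alone
  batch <- generate_records(gp, 5, seed = 50)
  expect_identical(batch[[3]], generate_record(gp, 52))
})

test_that("generated records validate and have a fixed 10-field base section", {
  schema <- ehr_schema()
  for (rec in qa_records(25)) {
    expect_true(validate_record(rec, schema))
    expect_length(rec$base, 10L)
  }
})

test_that("a 300-record batch matches the target population statistics", {
  st <- record_stats(qa_records(300))
  # mean total leaf fields within 15% of 240.1
  expect_lt(abs(mean(st$total) / 240.1 - 1), 0.15)
  # mean minified-JSON size within 20% of 7095 bytes
  expect_lt(abs(mean(st$json_bytes) / 7095 - 1), 0.20)
  # laboratory results are the dominant section by field count
  shares <- colMeans(st[, c("base", "operate", "image", "lab", "ass",
                            "disease", "drug")])
  expect_identical(names(which.max(shares)), "lab")
  expect_gt(shares[["lab"]] / mean(st$total), 0.5)
})

test_that("corpus lines hit the target length and CJK byte ratio", {
  corp <- qa_corpus()
  expect_identical(corp, generate_corpus(qa_generator(), seed = 1L,
                                         n_lines = 2000L))
  chars <- nchar(corp)
  bytes <- nchar(corp, type = "bytes")
  expect_lt(abs(mean(chars) / 38.3 - 1), 0.15)
  ratio <- mean(bytes) / mean(chars)
  expect_gte(ratio, 2.5)
  expect_lte(ratio, 3.0)
  expect_error(generate_corpus(qa_generator(), 1, 0),
               class = "qrstab_range_error")
})

test_that("train/test split is 9:1 and reproducible", {
  corp <- qa_corpus()
  sp1 <- train_test_split(corp, 0.9, seed = 3)
  sp2 <- train_test_split(corp, 0.9, seed = 3)
  expect_identical(sp1, sp2)
  expect_length(sp1$train, 1800L)
  expect_length(sp1$test, 200L)
  expect_setequal(c(sp1$train, sp1$test), corp)
})

test_that("corpus and records share vocabulary pools", {
  # a tokenizer trained on the corpus must compress record free text
  tok <- qa_bpe()
  recs <- qa_records(10)
  texts <- unlist(lapply(recs, function(r)
    c(vapply(r$lab, `[[`, character(1), "indicatorName"),
      vapply(r$image, `[[`, character(1), "conclusion"))))
  packed <- 2 * mean(lengths(encode_text_many(tok, texts)))
  utf8 <- mean(nchar(texts, type = "bytes"))
  expect_lt(packed, utf8)
})
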