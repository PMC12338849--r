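test_that("training is deterministic and merges never lengthen text", {
  tok <- train_tokenizer(rep("aaaa bbbb", 8), "bpe", vocab_size = 300)
  ids <- encode_text(tok, "aaaa bbbb")
  expect_lte(length(ids), nchar("aaaa bbbb"))
  expect_true(all(ids < 65536))

  tok2 <- train_tokenizer(rep("aaaa bbbb", 8), "bpe", vocab_size = 300)
  expect_identical(tok$merges, tok2$merges)

  corp <- qa_corpus()[1:200]
  u1 <- train_tokenizer(corp, "unigram", vocab_size = 600)
  u2 <- train_tokenizer(corp, "unigram", vocab_size = 600)
  expect_identical(u1$pieces, u2$pieces)
  expect_error(train_tokenizer(character(0), "bpe"),
               class = "qrstab_training_error")
})

test_that("byte fallback round-trips arbitrary unicode exactly", {
  models <- list(qa_bpe(), qa_unigram())
  set.seed(17)
  for (model in models) {
    expect_identical(encode_text(model, ""), integer(0))
    expect_identical(decode_text(model, integer(0)), "")
    s <- "Type 2 diabetes mellitus"
    ids <- encode_text(model, s)
    expect_lte(length(ids), 24L)
    expect_identical(decode_text(model, ids), s)
    for (i in 1:20) {
      cp <- sample(c(32:126, 0x4E00:0x9FA5, 0x3042:0x30FF, 0x1F600:0x1F640),
                   100, replace = TRUE)
      s <- intToUtf8(cp)
      expect_identical(decode_text(model, encode_text(model, s)), s)
    }
  }
})

test_that("BPE token economy is no worse than unigram's (within 5%)", {
  corp <- qa_corpus()
  nb <- mean(lengths(encode_text_many(qa_bpe(), corp)))
  nu <- mean(lengths(encode_text_many(qa_unigram(), corp)))
  expect_lte(nb, nu * 1.05)
})

test_that("packed tokens shrink corpus text below its UTF-8 size", {
  corp <- qa_corpus()
  utf8 <- mean(nchar(corp, type = "bytes"))
  packed <- 2 * mean(lengths(encode_text_many(qa_bpe(), corp)))
  expect_lt(packed, utf8)
})

test_that("token ids pack to big-endian 2-byte units", {
  expect_identical(pack_tokens(integer(0)), raw(0))
  expect_identical(pack_tokens(c(10L, 302L)),
                   as.raw(c(0x00, 0x0A, 0x01, 0x2E)))
  # independent big-endian arithmetic oracle
  set.seed(5)
  ids <- sample(0:65535, 500, replace = TRUE)
  oracle <- as.raw(as.vector(vapply(ids, function(x)
    c(x %/% 256, x %% 256), numeric(2))))
  expect_identical(pack_tokens(ids), oracle)
  expect_identical(unpack_tokens(pack_tokens(ids)), as.integer(ids))
  expect_identical(length(pack_tokens(ids)), 2L * length(ids))
  expect_error(pack_tokens(65536L), class = "qrstab_range_error")
  expect_error(unpack_tokens(as.raw(1:3)), class = "qrstab_framing_error")
})

test_that("tokenizer models persist to text files and reload identically", {
  dir <- withr::local_tempdir()
  for (model in list(qa_bpe(), qa_unigram())) {
    prefix <- file.path(dir, model$algorithm)
    save_tokenizer(model, prefix)
    back <- load_tokenizer(prefix)
    s <- qa_corpus()[5]
    expect_identical(encode_text(back, s), encode_text(model, s))
    expect_identical(back$pieces, model$pieces)
  }
})
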