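# Shared fixtures, built once per test run. Tokenizer training and record
# generation are deterministic, so caching them across test files changes
# nothing but wall time.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

qa_generator <- function() fixture("generator", generator_profile)

qa_corpus <- function() fixture("corpus", function()
  generate_corpus(qa_generator(), seed = 1L, n_lines = 2000L))

qa_bpe <- function() fixture("bpe", function()
  train_tokenizer(qa_corpus(), "bpe", vocab_size = 2000L, seed = 1L))

qa_unigram <- function() fixture("unigram", function()
  train_tokenizer(qa_corpus(), "unigram", vocab_size = 2000L, seed = 1L))

qa_profile <- function() fixture("profile", function()
  codec_profile(version = 1L, secret = random_secret(1234L),
                tokenizer = qa_bpe()))

# 300 records at the benchmark's design size; subset as needed
qa_records <- function(n = 300L) {
  all <- fixture("records", function()
    generate_records(qa_generator(), n = 300L, seed = 7L))
  all[seq_len(n)]
}

qa_record <- function(seed = 99L) generate_record(qa_generator(), seed = seed)

canon <- function(rec) canonicalize_record(rec, qa_profile()$schema)

# a record whose ciphertext is guaranteed to span several QR symbols:
# inflate the imaging section with long unpooled (incompressible) text
qa_big_record <- function(seed = 5L) {
  rec <- qa_record(seed)
  set.seed(seed)
  rec$image <- c(rec$image, lapply(1:8, function(i) list(
    examDate = "2024-03-01",
    examName = "MRI",
    bodyPart = "X",
    conclusion = paste(sample(c(letters, LETTERS, 0:9), 600, replace = TRUE),
                       collapse = "")
  )))
  rec
}
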