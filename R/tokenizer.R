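#' Train a byte-level subword tokenizer (BPE or unigram)
#'
#' Maps free-text field values to sequences of token ids below 65536 so each
#' token packs into a 2-byte unit inside the serialized record. Both
#' algorithms operate on raw UTF-8 bytes with the 256 single-byte tokens
#' permanently in the vocabulary (byte fallback), so every string — including
#' text never seen in training — round-trips exactly through
#' [encode_text()] / [decode_text()].
#'
#' `"bpe"` learns greedy pair merges by descending corpus frequency with a
#' deterministic tie-break; `"unigram"` seeds a vocabulary of frequent
#' substrings and refines piece probabilities by EM over Viterbi
#' segmentations, pruning back to `vocab_size`.
#'
#' @param corpus character vector of training lines (UTF-8).
#' @param algorithm `"bpe"` or `"unigram"`.
#' @param vocab_size maximum vocabulary size, 256-65535. The trained
#'   vocabulary may be smaller when the corpus supports fewer useful pieces.
#' @param seed integer recorded in the model metadata; training itself is
#'   deterministic given corpus and parameters.
#' @param max_piece_len longest unigram piece in bytes.
#' @return A `qrstab_tokenizer`: algorithm, piece table, merge table (BPE) or
#'   scores (unigram), and metadata including a corpus digest.
#' @export
#' @examples
#' tok <- train_tokenizer(rep("aaaa bbbb", 5), "bpe", vocab_size = 300)
#' encode_text(tok, "aaaa bbbb")
train_tokenizer <- function(corpus, algorithm = c("bpe", "unigram"),
                            vocab_size = 8192L, seed = 1L,
                            max_piece_len = 12L) {
  algorithm <- match.arg(algorithm)
  corpus <- enc2utf8(as.character(corpus))
  corpus <- corpus[!is.na(corpus) & nzchar(corpus)]
  if (length(corpus) == 0L)
    qrstab_error("qrstab_training_error", "training corpus is empty")
  vocab_size <- assert_count(vocab_size, "vocab_size", 256L, 65535L)

  tab <- table(corpus)
  uniq <- names(tab)
  counts <- as.integer(tab)
  seqs <- lapply(uniq, charToRaw)
  corpus_hash <- raw_to_hex(blake3(charToRaw(paste(corpus, collapse = "\n")),
                                   length = 16L))

  if (algorithm == "bpe") {
    merges <- .bpe_train(seqs, counts, vocab_size)
    pieces <- bpe_pieces(merges)
    scores <- NULL
  } else {
    fit <- .unigram_train(seqs, counts, vocab_size, as.integer(max_piece_len), 3L)
    pieces <- fit$pieces
    scores <- fit$scores
    merges <- NULL
  }
  structure(
    list(algorithm = algorithm, pieces = pieces, merges = merges,
         scores = scores,
         metadata = list(vocab_size = vocab_size, seed = as.integer(seed),
                         corpus_hash = corpus_hash,
                         n_lines = length(corpus),
                         max_piece_len = as.integer(max_piece_len))),
    class = "qrstab_tokenizer"
  )
}

# expand the merge table into the byte string of every token id
bpe_pieces <- function(merges) {
  pieces <- lapply(0:255, function(b) as.raw(b))
  if (nrow(merges) > 0L)
    for (k in seq_len(nrow(merges)))
      pieces[[256L + k]] <- c(pieces[[merges[k, 1L] + 1L]],
                              pieces[[merges[k, 2L] + 1L]])
  pieces
}

#' Encode text to token ids / decode token ids to text
#'
#' Byte fallback guarantees coverage: encoding never fails and
#' `decode_text(model, encode_text(model, s))` reproduces `s` byte-exactly
#' for arbitrary input.
#'
#' @param model a trained [train_tokenizer()] model.
#' @param text a character scalar.
#' @return `encode_text()`: an integer vector of token ids (< 65536);
#'   `decode_text()`: the reconstructed string.
#' @export
encode_text <- function(model, text) {
  stopifnot(inherits(model, "qrstab_tokenizer"))
  encode_text_many(model, text)[[1L]]
}

#' @rdname encode_text
#' @param texts character vector (batch interface).
#' @export
encode_text_many <- function(model, texts) {
  raws <- lapply(enc2utf8(as.character(texts)), charToRaw)
  if (model$algorithm == "bpe")
    .bpe_encode_many(raws, model$merges)
  else
    .unigram_encode_many(raws, model$pieces, model$scores)
}

#' @rdname encode_text
#' @param ids integer vector of token ids.
#' @export
decode_text <- function(model, ids) {
  stopifnot(inherits(model, "qrstab_tokenizer"))
  if (length(ids) == 0L) return("")
  if (any(ids < 0L | ids >= length(model$pieces)))
    stop_range("token id outside the model vocabulary")
  out <- rawToChar(do.call(c, model$pieces[ids + 1L]))
  Encoding(out) <- "UTF-8"
  out
}

#' Pack token ids into fixed 2-byte big-endian units
#'
#' Each token id occupies exactly 2 bytes, so `length(output) == 2 *
#' length(ids)`. [unpack_tokens()] is the exact inverse; an odd-length input
#' is a framing error.
#'
#' @param ids integer vector, all ids < 65536.
#' @return Raw vector of `2 * length(ids)` bytes.
#' @export
#' @examples
#' pack_tokens(c(10L, 302L)) # 00 0a 01 2e
pack_tokens <- function(ids) {
  if (length(ids) == 0L) return(raw(0))
  ids <- as.integer(ids)
  if (any(is.na(ids) | ids < 0L | ids > 65535L))
    stop_range("token ids must lie in [0, 65535] to pack into 2-byte units")
  as.raw(rbind(ids %/% 256L, ids %% 256L))
}

#' @rdname pack_tokens
#' @param bytes raw vector of even length.
#' @export
unpack_tokens <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) %% 2L != 0L)
    stop_framing("packed token stream must have even length")
  if (length(bytes) == 0L) return(integer(0))
  m <- matrix(as.integer(bytes), nrow = 2L)
  as.integer(m[1L, ] * 256L + m[2L, ])
}

#' Persist / load a tokenizer model
#'
#' The model is written as a plain-text piece table (`<prefix>.model`: one
#' hex-encoded piece per line with its merge rank or log-probability) plus a
#' JSON metadata sidecar (`<prefix>.json`).
#'
#' @param model a `qrstab_tokenizer`.
#' @param prefix file path prefix (without extension).
#' @export
save_tokenizer <- function(model, prefix) {
  stopifnot(inherits(model, "qrstab_tokenizer"))
  if (model$algorithm == "bpe") {
    lines <- apply(model$merges, 1L, function(r) sprintf("%d\t%d", r[1L], r[2L]))
  } else {
    lines <- vapply(seq_along(model$pieces), function(i)
      sprintf("%s\t%.17g", raw_to_hex(model$pieces[[i]]), model$scores[i]),
      character(1))
  }
  writeLines(c(model$algorithm, lines), paste0(prefix, ".model"))
  jsonlite::write_json(model$metadata, paste0(prefix, ".json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname save_tokenizer
#' @export
load_tokenizer <- function(prefix) {
  lines <- readLines(paste0(prefix, ".model"))
  algorithm <- lines[1L]
  body <- lines[-1L]
  metadata <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (algorithm == "bpe") {
    parts <- if (length(body)) do.call(rbind, strsplit(body, "\t", fixed = TRUE))
             else matrix(character(0), ncol = 2)
    merges <- matrix(as.integer(parts), ncol = 2L)
    model <- list(algorithm = "bpe", pieces = bpe_pieces(merges),
                  merges = merges, scores = NULL, metadata = metadata)
  } else {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    model <- list(algorithm = "unigram",
                  pieces = lapply(parts[, 1L], hex_to_raw),
                  merges = NULL, scores = as.numeric(parts[, 2L]),
                  metadata = metadata)
  }
  structure(model, class = "qrstab_tokenizer")
}

#' @export
print.qrstab_tokenizer <- function(x, ...) {
  cat(sprintf("<qrstab_tokenizer> %s, %d pieces (vocab_size %d), trained on %d lines\n",
              x$algorithm, length(x$pieces), x$metadata$vocab_size,
              x$metadata$n_lines))
  invisible(x)
}
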