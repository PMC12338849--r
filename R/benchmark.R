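#' Compression ratio
#'
#' Original bytes divided by compressed bytes — the protocol's headline
#' efficiency metric. A ratio above 1 means the pipeline shrank the record.
#'
#' @param orig_bytes original size in bytes.
#' @param comp_bytes compressed size in bytes (>= 1).
#' @return Numeric ratio.
#' @export
#' @examples
#' compression_ratio(185, 38) # ~4.87
compression_ratio <- function(orig_bytes, comp_bytes) {
  if (any(comp_bytes < 1)) stop_range("compressed size must be at least 1 byte")
  orig_bytes / comp_bytes
}

#' Benchmark the pipeline combinations on a set of records
#'
#' For every record, measures the minified-JSON original size and the
#' output size under five pipelines: Gzip on the raw JSON (`gzip`), binary
#' serialization alone (`serial`), serialization + Gzip (`serial_gzip`),
#' serialization with tokenized text (`serial_bpe`), and the full
#' serialization + tokenization + Gzip combination (`serial_bpe_gzip`).
#' Every combination's output is decoded back and checked equal to the
#' source record before its size counts. Aggregates report per-record ratio
#' statistics (mean, median, IQR, min, max), the ratio of total bytes, and
#' paired two-sided t-tests between the headline pipeline pairs.
#'
#' @param records list of records (e.g. [generate_records()]).
#' @param profile a [codec_profile()] whose tokenizer was trained on a
#'   corpus sharing the records' vocabulary.
#' @return A `qrstab_benchmark`: `per_record` data frame, `summary` data
#'   frame, `tests` (paired t-tests), `totals`.
#' @export
run_combos <- function(records, profile) {
  stopifnot(inherits(profile, "qrstab_profile"))
  if (is.null(profile$tokenizer))
    qrstab_error("qrstab_benchmark_error",
                 "profile must carry a trained tokenizer")
  schema <- profile$schema
  tok <- profile$tokenizer
  epoch <- profile$tag_epoch
  combos <- c("gzip", "serial", "serial_gzip", "serial_bpe", "serial_bpe_gzip")

  rows <- lapply(seq_along(records), function(i) {
    rec <- canonicalize_record(records[[i]], schema)
    json_raw <- charToRaw(enc2utf8(record_to_json(rec, schema)))
    orig <- length(json_raw)
    ser_plain <- serialize_record(rec, schema, NULL, epoch)
    ser_tok <- serialize_record(rec, schema, tok, epoch)
    sizes <- c(
      gzip = length(gzip_compress(json_raw)),
      serial = length(ser_plain),
      serial_gzip = length(gzip_compress(ser_plain)),
      serial_bpe = length(ser_tok),
      serial_bpe_gzip = length(gzip_compress(ser_tok))
    )
    # every arm must reproduce the source record exactly
    ok <- identical(record_from_json(rawToChar(gzip_decompress(gzip_compress(json_raw))), schema), rec) &&
      identical(deserialize_record(ser_plain, schema, NULL, epoch), rec) &&
      identical(deserialize_record(ser_tok, schema, tok, epoch), rec)
    if (!ok)
      qrstab_error("qrstab_benchmark_error",
                   sprintf("round-trip failure at record %d", i))
    c(orig_bytes = orig, sizes)
  })
  per <- as.data.frame(do.call(rbind, rows))
  for (cb in combos)
    per[[paste0("ratio_", cb)]] <- compression_ratio(per$orig_bytes, per[[cb]])

  summarise <- function(r) {
    q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(r), median = q[2L], q1 = q[1L], q3 = q[3L],
      min = min(r), max = max(r))
  }
  summary_df <- as.data.frame(t(vapply(
    combos, function(cb) summarise(per[[paste0("ratio_", cb)]]),
    numeric(6))))
  totals <- vapply(combos, function(cb)
    sum(per$orig_bytes) / sum(per[[cb]]), numeric(1))

  tests <- list(
    combined_vs_gzip = stats::t.test(per$ratio_serial_bpe_gzip,
                                     per$ratio_gzip, paired = TRUE),
    bpe_effect = stats::t.test(per$ratio_serial_bpe_gzip,
                               per$ratio_serial_gzip, paired = TRUE),
    gzip_over_serial = stats::t.test(per$ratio_serial_gzip,
                                     per$ratio_serial, paired = TRUE)
  )
  structure(list(per_record = per, summary = summary_df,
                 totals = totals, tests = tests, n = length(records)),
            class = "qrstab_benchmark")
}

#' Distribution of QR codes needed per record
#'
#' Applies [compute_count()] to each record's final compressed size under
#' the configured symbol capacity (with the 6-byte header reserved) and
#' tabulates the histogram and cumulative distribution — the "how many
#' codes must a patient scan" curve.
#'
#' @param result a [run_combos()] result.
#' @param cfg a [qr_config()].
#' @param combo which pipeline's sizes to use (default the full pipeline).
#' @return A list: `counts` (per record), `histogram`, `cdf`,
#'   `share_single` (fraction of records fitting one QR code).
#' @export
qr_count_distribution <- function(result, cfg = qr_config(),
                                  combo = "serial_bpe_gzip") {
  stopifnot(inherits(result, "qrstab_benchmark"))
  capacity <- qr_capacity(cfg$version, cfg$ec_level)
  counts <- vapply(result$per_record[[combo]], compute_count, integer(1),
                   qr_capacity = capacity, header_len = 6L)
  tab <- table(factor(counts, levels = seq_len(max(counts))))
  list(counts = counts,
       histogram = tab,
       cdf = cumsum(tab) / length(counts),
       share_single = mean(counts == 1L))
}

#' @export
print.qrstab_benchmark <- function(x, ...) {
  cat(sprintf("<qrstab_benchmark> %d records, mean original %.0f bytes\n",
              x$n, mean(x$per_record$orig_bytes)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s mean %.2f  median %.2f (IQR %.2f-%.2f)  range %.2f-%.2f\n",
                rownames(s)[i], s$mean[i], s$median[i], s$q1[i], s$q3[i],
                s$min[i], s$max[i]))
  cat(sprintf("  ratio of totals (full pipeline): %.2f\n",
              x$totals[["serial_bpe_gzip"]]))
  cat(sprintf("  paired t-test full vs gzip: p = %.3g\n",
              x$tests$combined_vs_gzip$p.value))
  invisible(x)
}
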