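Package: qrstab
Title: Secure QR-Code Transmission of Structured Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encoder and decoder for a paper-based health-information
    exchange protocol that carries deidentified electronic health records
    across air-gapped networks inside printed QR codes. Records pass through
    a multistage pipeline: subword tokenization (byte-level BPE or unigram)
    of free-text fields, schema-driven binary serialization with zig-zag
    varints, deflate compression, ChaCha20 stream encryption, and splitting
    into QR symbols framed by an authenticated 6-byte header carrying a
    truncated BLAKE3 fingerprint. Includes the decoder-side reassembly
    session with status reporting, a seeded synthetic record and corpus
    generator, and a compression benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
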