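---
title: "qrstab: protocol design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qrstab: protocol design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of how the codec works, which
parameters matter, where the design was genuinely open and what was decided,
and what the synthetic evaluation can and cannot demonstrate. The worked
numbers in the README are produced by the code shown there; this document
states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## Problem setting and threat model

The package moves a deidentified structured health record from an isolated
hospital network to a patient-facing system with no network path between
them: the record is printed as QR codes on the paper discharge report. The
channel is public — anyone can photograph the paper — so the payload must
be confidential, bound to its intended recipient, and compact enough that a
typical record fits one or two symbols.

Both ends hold a **codec profile**, synchronized offline: a 256-bit secret,
the record schema, a trained tokenizer, a tag-epoch date, and the QR
transport configuration. Security rests entirely on this shared material;
there is no key exchange in-band. The identity string used in the packet
fingerprint is *not* secret — it binds a scan to the logged-in account, it
does not encrypt for it.

## The pipeline and its contracts

Encoding is `tokenize → serialize → deflate → encrypt → split →
fingerprint`, and every stage is an exact bijection on its domain, so
decode∘encode is the identity on schema-valid records. The stage contracts
worth spelling out:

* **Tokenization** operates on raw UTF-8 bytes with the 256 single-byte
  tokens permanently in the vocabulary. This byte fallback is what makes
  the round trip unconditional — out-of-vocabulary characters degrade
  compression, never correctness. Token ids are packed as fixed 2-byte
  big-endian units rather than varints: frequent pieces get large ids, and
  varint coding would re-inflate exactly the ids a good tokenizer uses
  most.
* **Serialization** writes Avro binary wire format (zig-zag varints,
  length-prefixed bytes, block-coded arrays, union branch indices) against
  a schema that never travels with the data. Dates are day offsets from
  the profile epoch; decimal measurements (height, weight, BMI, lab
  values, doses) are scaled integers with a declared number of decimal
  places. Scaled integers rather than IEEE floats are a deliberate choice:
  they make serialize/deserialize bit-exact and keep JSON equality
  trivial.
* **Encryption** is the original 64-bit-nonce ChaCha20. The stream cipher
  preserves length, so the only expansion in the whole
  encrypt-and-authenticate layer is the 2-byte truncated BLAKE3
  fingerprint in each header — the quantity `scripts/acceptance.R`
  measures.
* **Packetization** reserves 6 header bytes out of every symbol, so a
  version-25/L code carries 1267 body bytes. The 4-bit count field caps a
  transmission at 15 symbols; at that point the record should be shrunk,
  not the protocol stretched.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `vocab_size` | 8192 (training); 65535 max | tokens | ids must fit 2 bytes; larger vocabularies compress better but train and load slower |
| QR `version` / `ec_level` | 25 / L | — | 1273-byte capacity; L maximizes payload, acceptable for clean prints |
| `module_px` / `dpi` | 4 px / 200 dpi | — | 4×4-pixel modules print reliably on office printers; yields a 2.5 in theoretical edge |
| `quiet_zone` | 4 | modules | QR specification minimum |
| `redundancy` | 0.20 | fraction | print-size reserve for printer variation → 7.62 cm designed edge |
| `fingerprint_len` | 2 | bytes | false-accept 2^-16; the v1 6-byte header has a 16-bit tag field |
| `tag_epoch` | 2020-01-01 | date | transaction ids are day offsets; 16 bits cover ~179 years |

## Design decisions in the open spots

**Nonce derivation.** The header has no nonce field and the overhead budget
is 2 bytes, so the nonce cannot be transmitted. Both ends derive it: a
subkey is the keyed-BLAKE3 digest of a fixed label under the shared
secret, and the nonce is the first 8 bytes of the keyed digest, under that
subkey, of `version ‖ transaction ‖ count`. This is deterministic and
requires no state. The documented limitation: two *different* messages
sharing all three values — e.g. two same-day transmissions for one
admission whose bodies also split into the same packet count — would reuse
a keystream. Deployments that re-issue reports should bump the version
byte or extend the transaction derivation.

**Per-packet authentication over ciphertext.** The decoder must be able to
reject a packet *before* decrypting (authenticate-then-decrypt), and
packets arrive in any order, so the fingerprint covers each ciphertext
chunk concatenated with the recipient identity, not the assembled
plaintext. Identity strings enter as exact UTF-8 bytes, no normalization.

**Transaction encoding.** The transaction id is the whole-day count from
the tag epoch to the admission date, stored big-endian unsigned 16-bit.
Day-offset is the only dimensionally coherent reading of "admission date
combined with an epoch date" and gives stable ids across re-encodings.
Collisions are possible (two admissions, same day); the decoder therefore
keys buffers by `(version, transaction)` and flags same-slot conflicts as
`exception` rather than silently merging.

**Status precedence.** The six response codes are ordered `tag_error`
(framing/unknown version) → `auth_failed` (fingerprint) → `duplicated`
(byte-identical repeat) → `waiting`/`finished`, with every
post-authentication failure mapped to `exception`. Failing fastest leaks
least: an attacker probing with malformed packets learns only that they
are malformed. A repeated seq with *different* bytes is `exception`, not
`duplicated` — that pattern is tampering, not a double scan. After a
failed final decode the transaction buffer is dropped so the user can
rescan cleanly; `finished` is emitted exactly once per transaction.

**Count stored raw.** The count nibble holds 1–15 with 0 reserved, rather
than a biased count−1 encoding that would allow 16. The off-by-one
ambiguity is worth more than the sixteenth packet: 15 × 1267 bytes is far
beyond any record this codec is for.

**QR rendering support.** Symbols are rendered and decoded at error
correction level L only — the level the transport actually uses, since L
maximizes capacity and the operating premise is clean rasters/prints, not
damaged labels. Capacity lookup (`qr_capacity()`) covers all four levels
and all 40 versions. The mask pattern is fixed at 0 with correct format
information (the reader honours whatever the format info declares);
penalty-score mask optimization improves worst-case scanner ergonomics,
not correctness, and is omitted. The decoder targets pristine images: it
locates the symbol by quiet-zone cropping, infers the version from the
module count, verifies the finder patterns, and *verifies* Reed–Solomon
syndromes rather than correcting errors — a damaged symbol is a scan
error, never silently wrong bytes.

**Schema shape.** The base section carries exactly ten non-identifying
fields (age, gender, height, weight, BMI, department, stay length,
admission/discharge dates, admission type); the six clinical sections are
arrays that may be empty. The schema is versioned and fingerprinted
(truncated BLAKE3 of the canonical schema JSON) inside the profile, and
schema mismatch is checked out-of-band when a profile directory is loaded
— the wire stream itself carries no self-description, which is both the
compression and the information-hiding property.

## The synthetic data: what it emulates, what it does not

No real records ship with or are fetched by this package. The generator
(`generator_profile()`, `generate_record()`, `generate_corpus()`) emulates
the *summary shape* of the clinical population the protocol was designed
around:

* ~240 leaf fields per record on average (range roughly 90–620), with
  laboratory results the dominant section (~2/3 of fields), and a fixed
  10-field base section;
* ~7 kB of minified JSON per record on average (roughly 3–17 kB range);
* a tokenizer corpus of short clinical sentences, ~38 characters each,
  CJK-dominant with ~10% ASCII so a character averages ~2.8 UTF-8 bytes;
* per-section item counts drawn from truncated negative-binomial-type
  distributions matched to the section means and ranges — the real
  distribution family is unknown; any family matching mean and range is
  admissible and this one is recorded in the profile;
* text drawn from fixed phrase pools over a ~400-ideograph character
  inventory, shared between records and corpus. The limited inventory and
  pooled phrases reproduce the two properties that drive subword
  compression on real clinical text: heavy character reuse and heavy
  phrase repetition.

What it does **not** emulate: real medical vocabulary and its frequency
structure, correlations between sections (a thrombosis diagnosis does not
make D-dimer labs more likely), longitudinal structure, or free text
written by humans. Consequently, *absolute* compression ratios on
synthetic data do not transfer to real records — with a reduced test
vocabulary the full pipeline lands near 4.7× here versus ~2.6× for plain
gzip — and only the orderings and structural properties (combined pipeline
beats gzip; serialization alone is >1; BPE's token economy is at least
unigram-adjacent; larger records compress relatively better) are asserted
by tests. Round-trip correctness, by contrast, transfers completely: it is
exercised over arbitrary bytes and arbitrary Unicode, not just generator
output.

## Numerical and implementation choices

* **Deterministic deflate.** Compression goes through zlib's gzip framing
  via `memCompress()`, which writes a zero mtime — equal input, equal
  bytes, across sessions and platforms.
* **BPE tie-breaks.** When two pairs tie on corpus frequency, the smaller
  (left, right) id pair wins; training is therefore a pure function of the
  corpus and parameters (the recorded seed is metadata, not an entropy
  source). Encoding applies merges strictly in training order.
* **Unigram training** seeds candidate pieces from frequent substrings (up
  to 12 bytes), runs a small number of EM rounds of Viterbi segmentation
  and usage re-estimation, and anneals the vocabulary down to the target
  size, always retaining the 256 byte tokens.
* **Varint edges.** `zigzag_decode` rejects empty input, truncated
  sequences, and varints longer than 10 bytes; the deserializer rejects
  trailing bytes, so a stream is either exactly one record or an error.
* **Degenerate inputs.** Empty message bodies are rejected at
  `compute_count` (an empty record still serializes to >0 bytes); empty
  strings tokenize to the empty id sequence; empty sections serialize as
  an empty array block.
* **Reed–Solomon** arithmetic is over GF(2^8) with the 0x11D reduction
  polynomial using log/antilog tables; generator polynomials are cached
  per EC length. The symbol tables (capacities, level-L block structures,
  alignment coordinates) are validated in the test suite against an
  independent geometry computation — total codewords counted from
  non-function modules of the constructed matrix — and against the
  capacity-implied data codeword arithmetic, for every version.

## Problem sizes used by the tests

The suite trains both tokenizer algorithms at vocabulary 2000 on a
2000-line corpus, round-trips several hundred records through every stage,
runs the end-to-end encode–scan–decode identity over 200 seeded records
plus forced multi-packet and permutation cases, enumerates the full 16-bit
tag space and 2×10^6 random forgeries for the false-accept bound, and runs
the benchmark arms on 300 records — sizes chosen so the whole suite runs
in well under two minutes on one CPU while still estimating every rate it
asserts. The acceptance script touches only the encryption layer and is
effectively instant.

## Known limitations

* Keystream reuse under a repeated `(version, transaction, count)` triple,
  discussed above.
* A 2-byte tag authenticates against casual misuse and mis-scans, not
  against an adversary submitting 2^16 forgeries to an unthrottled
  decoder; deployments should rate-limit scan endpoints.
* The QR reader handles clean rasters (its own renders, lossless scans),
  not photographs: no perspective correction, no error *correction*.
* `fingerprint_len` values other than 2 are valid for the hash primitive
  but do not fit the version-1 6-byte header; a future header version
  would have to widen the tag field.
* Schema evolution (reader and writer on different schema versions) is out
  of scope; version bytes select whole profiles instead.
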