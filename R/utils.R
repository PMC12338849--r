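`%||%` <- function(a, b) if (is.null(a)) b else a

qrstab_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "qrstab_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_range <- function(msg) qrstab_error("qrstab_range_error", msg)
stop_framing <- function(msg) qrstab_error("qrstab_framing_error", msg)
stop_capacity <- function(msg) qrstab_error("qrstab_capacity_error", msg)

assert_count <- function(x, name, min = 0L, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x))
    stop_range(sprintf("%s must be a single integer", name))
  if (x < min || x > max)
    stop_range(sprintf("%s = %s out of range [%s, %s]", name, x, min, max))
  as.integer(x)
}

#' @noRd
int_to_raw_be <- function(x, width) {
  x <- as.numeric(x)
  out <- raw(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' @noRd
raw_to_int_be <- function(r) {
  v <- 0
  for (b in as.integer(r)) v <- v * 256 + b
  v
}

#' Hex helpers for keys and digests
#'
#' @param r raw vector.
#' @param s hex string (non-hex characters such as whitespace are ignored).
#' @return `raw_to_hex()` returns a lowercase hex string; `hex_to_raw()` a
#'   raw vector.
#' @export
raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

#' @rdname raw_to_hex
#' @export
hex_to_raw <- function(s) {
  s <- gsub("[^0-9a-fA-F]", "", s)
  if (nchar(s) %% 2L != 0L) stop_framing("hex string has odd length")
  as.raw(strtoi(substring(s, seq(1, nchar(s), 2), seq(2, nchar(s), 2)), 16L))
}

# run code under a temporary RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
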