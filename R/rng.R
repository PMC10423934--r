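#' Deterministic 31-bit hash of a key tuple
#'
#' Maps an arbitrary tuple of atomic values to an integer in
#' `[0, 2^31 - 2]`, used to derive independent, reproducible RNG
#' substreams from a master seed plus identifying labels (for example
#' `(master_seed, video_id, piece_index)`). The hash is a DJB2-style
#' polynomial over the UTF-8 bytes of the fields joined with an
#' unprintable separator, reduced mod 2^31 - 1, so it is stable across
#' platforms and R versions and never collides two tuples that differ
#' only by field concatenation.
#'
#' Deriving per-entity seeds this way means adding one more video to a
#' dataset never perturbs the chunks sampled for any other video.
#'
#' @param ... atomic values (coerced to character) identifying the stream.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' hash_seed(42, "video_a", 0)
#' hash_seed(42, "video_a", 1) # independent stream for the next piece
hash_seed <- function(...) {
  parts <- vapply(list(...), function(p) paste(as.character(p), collapse = ","),
                  character(1))
  s <- paste(parts, collapse = "\x1f")
  bytes <- utf8ToInt(s)
  h <- 5381
  # 33 * (2^31 - 2) + 255 < 2^53: exact in double arithmetic
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate code under a seeded, isolated RNG substream
#'
#' Runs `code` with the RNG seeded from `hash_seed(...)` of the supplied
#' key tuple, restoring the caller's RNG state afterwards (via
#' [withr::with_seed()]).
#'
#' @param ... key tuple passed to [hash_seed()].
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_substream <- function(..., code) {
  withr::with_seed(hash_seed(...), code)
}
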