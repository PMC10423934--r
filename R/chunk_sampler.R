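#' Sampling parameters for the Piece/Chunk randomization
#'
#' A recording is split into `pieces_n` contiguous Pieces of
#' `piece_dur_s` seconds each; within every Piece, `chunks_per_piece`
#' non-overlapping Chunks of `chunk_dur_s` seconds are drawn uniformly
#' at random. Stratifying the draw by Piece keeps behaviors that cluster
#' early or late in an assay (e.g. pup retrieval) represented evenly.
#' Defaults give 3 x 10 min pieces and 10 x 10 s chunks per piece: 30
#' chunks, 5 min scored per 30-min recording.
#'
#' @param pieces_n number of pieces (>= 1; use 1 to disable stratification).
#' @param piece_dur_s piece duration, seconds.
#' @param chunks_per_piece chunks drawn per piece (>= 0).
#' @param chunk_dur_s chunk duration, seconds (> 0).
#' @param master_seed integer master seed; per-piece streams are derived
#'   from `(master_seed, video_id, piece_index)` via [hash_seed()].
#' @return an object of class `sampling_params`.
#' @export
sampling_params <- function(pieces_n = 3L, piece_dur_s = 600,
                            chunks_per_piece = 10L, chunk_dur_s = 10,
                            master_seed = 0L) {
  stopifnot(pieces_n >= 1, chunk_dur_s > 0, chunks_per_piece >= 0,
            piece_dur_s > 0)
  n_slots <- floor(piece_dur_s / chunk_dur_s)
  if (chunks_per_piece > n_slots) {
    stop(sprintf(
      "chunks_per_piece (%d) exceeds the %d non-overlapping slots of length %g s in a %g s piece",
      as.integer(chunks_per_piece), as.integer(n_slots), chunk_dur_s, piece_dur_s
    ), call. = FALSE)
  }
  structure(
    list(pieces_n = as.integer(pieces_n), piece_dur_s = as.numeric(piece_dur_s),
         chunks_per_piece = as.integer(chunks_per_piece),
         chunk_dur_s = as.numeric(chunk_dur_s),
         master_seed = as.integer(master_seed)),
    class = "sampling_params"
  )
}

#' Partition a recording into contiguous piece windows
#'
#' Produces `pieces_n` half-open windows `[k*piece_dur_s, (k+1)*piece_dur_s)`
#' anchored at 0. Recording time beyond the last piece is excluded with a
#' logged message (recordings often overrun slightly); a recording shorter
#' than the required span is an error.
#'
#' @param duration_s recording duration, seconds.
#' @param params a [sampling_params()].
#' @return tibble with columns `piece_index` (0-based), `start_s`, `stop_s`.
#' @export
#' @examples
#' partition_pieces(1800, sampling_params())
partition_pieces <- function(duration_s, params = sampling_params()) {
  stopifnot(inherits(params, "sampling_params"))
  required <- params$pieces_n * params$piece_dur_s
  if (duration_s < required) {
    stop(sprintf(
      "recording of %g s too short: %d pieces of %g s require at least %g s",
      duration_s, params$pieces_n, params$piece_dur_s, required
    ), call. = FALSE)
  }
  if (duration_s > required) {
    message(sprintf("excluding trailing %g s beyond the %g s piece span",
                    duration_s - required, required))
  }
  k <- seq_len(params$pieces_n) - 1L
  tibble(piece_index = k,
         start_s = k * params$piece_dur_s,
         stop_s = (k + 1) * params$piece_dur_s)
}

#' Draw a stratified random sampling plan for one recording
#'
#' Each piece is tiled into `floor(piece_dur_s / chunk_dur_s)` aligned,
#' non-overlapping slots; `chunks_per_piece` distinct slots are drawn
#' uniformly without replacement from a deterministic substream seeded by
#' `(master_seed, video_id, piece_index)`. The same inputs always yield
#' the identical plan, and adding another video never changes this one's
#' draw.
#'
#' @param video_id recording identifier.
#' @param duration_s recording duration, seconds.
#' @param params a [sampling_params()].
#' @return an object of class `sampling_plan` with fields `video_id`,
#'   `params`, and `chunks` (tibble: `video_id`, `chunk_id`,
#'   `piece_index`, `start_s`, `dur_s`).
#' @export
#' @examples
#' plan <- sample_chunks("damA_ld1", 1800, sampling_params(master_seed = 7))
#' nrow(plan$chunks)
sample_chunks <- function(video_id, duration_s, params = sampling_params()) {
  stopifnot(inherits(params, "sampling_params"))
  pieces <- partition_pieces(duration_s, params)
  n_slots <- as.integer(floor(params$piece_dur_s / params$chunk_dur_s))
  chunks <- lapply(seq_len(nrow(pieces)), function(i) {
    pi <- pieces$piece_index[i]
    slots <- with_substream(params$master_seed, video_id, pi, code = {
      sort(sample.int(n_slots, params$chunks_per_piece))
    }) - 1L
    tibble(
      video_id = video_id,
      chunk_id = sprintf("p%d_s%03d", pi, slots),
      piece_index = pi,
      start_s = pieces$start_s[i] + slots * params$chunk_dur_s,
      dur_s = params$chunk_dur_s
    )
  })
  plan <- structure(
    list(video_id = as.character(video_id), params = params,
         chunks = do.call(rbind, chunks)),
    class = "sampling_plan"
  )
  validate_sampling_plan(plan)
  plan
}

#' Validate a sampling plan's structural invariants
#'
#' Checks chunk count, equal count per piece, containment of each chunk
#' in its piece window, and pairwise non-overlap.
#'
#' @param plan a `sampling_plan`.
#' @return `plan`, invisibly; errors on violation.
#' @export
validate_sampling_plan <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  p <- plan$params
  ch <- plan$chunks
  expected <- p$pieces_n * p$chunks_per_piece
  if (nrow(ch) != expected) {
    stop(sprintf("plan has %d chunks; expected pieces_n x chunks_per_piece = %d",
                 nrow(ch), expected), call. = FALSE)
  }
  per_piece <- table(factor(ch$piece_index, levels = seq_len(p$pieces_n) - 1L))
  if (any(per_piece != p$chunks_per_piece)) {
    stop("unequal chunk counts across pieces", call. = FALSE)
  }
  piece_lo <- ch$piece_index * p$piece_dur_s
  if (any(ch$start_s < piece_lo | ch$start_s + ch$dur_s > piece_lo + p$piece_dur_s)) {
    stop("chunk extends outside its piece window", call. = FALSE)
  }
  o <- order(ch$start_s)
  s <- ch$start_s[o]; e <- ch$start_s[o] + ch$dur_s[o]
  if (nrow(ch) > 1L && any(s[-1L] < e[-nrow(ch)])) {
    stop("overlapping chunks within one video", call. = FALSE)
  }
  invisible(plan)
}

PLAN_COLUMNS <- c("video_id", "chunk_id", "piece_index", "start_s", "dur_s")

#' Write / read a sampling plan (CSV round-trip)
#'
#' Sampling parameters travel in `# key=value` header comment lines;
#' chunk rows follow in the documented column order
#' `video_id,chunk_id,piece_index,start_s,dur_s`. Reading re-validates
#' all plan invariants, so a hand-edited plan with overlapping chunks is
#' rejected.
#'
#' @param plan a `sampling_plan`.
#' @param path file path.
#' @return `write_plan`: `path`, invisibly. `read_plan`: a `sampling_plan`.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "sampling_plan"))
  p <- plan$params
  meta <- c(pieces_n = p$pieces_n, piece_dur_s = p$piece_dur_s,
            chunks_per_piece = p$chunks_per_piece, chunk_dur_s = p$chunk_dur_s,
            master_seed = p$master_seed)
  ch <- plan$chunks
  lines <- c(
    sprintf("# %s=%s", names(meta), unname(as.character(meta))),
    paste(PLAN_COLUMNS, collapse = ","),
    sprintf("%s,%s,%d,%s,%s", ch$video_id, ch$chunk_id, ch$piece_index,
            fmt_s(ch$start_s), fmt_s(ch$dur_s))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  meta <- parse_meta_block(lines)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  miss <- setdiff(PLAN_COLUMNS, header)
  if (length(miss) > 0L) {
    stop("plan CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  params <- sampling_params(
    pieces_n = as.integer(meta[["pieces_n"]]),
    piece_dur_s = as.numeric(meta[["piece_dur_s"]]),
    chunks_per_piece = as.integer(meta[["chunks_per_piece"]]),
    chunk_dur_s = as.numeric(meta[["chunk_dur_s"]]),
    master_seed = as.integer(meta[["master_seed"]])
  )
  plan <- structure(
    list(video_id = df$video_id[1L], params = params,
         chunks = as_tibble(df[, PLAN_COLUMNS])),
    class = "sampling_plan"
  )
  validate_sampling_plan(plan)
  plan
}
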