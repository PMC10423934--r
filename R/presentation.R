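int_to_base36 <- function(x, width = 4L) {
  alphabet <- c(0:9, LETTERS)
  vapply(x, function(v) {
    d <- character(width)
    for (i in seq_len(width)) {
      d[width - i + 1L] <- alphabet[v %% 36L + 1L]
      v <- v %/% 36L
    }
    paste(d, collapse = "")
  }, character(1))
}

#' Build a blinded, randomly ordered presentation schedule
#'
#' Pools the chunks of several sampling plans and assigns (i) a uniformly
#' random presentation order and (ii) an opaque fixed-length blind code
#' per chunk, both from seeded, reproducible streams. The scorer works
#' from `(presentation_rank, blind_code, dur_s)` alone and so cannot
#' infer animal, group, day, or a chunk's position within its recording;
#' the `blind_map` linking codes back to `(video_id, chunk_id)` is kept
#' as a separate artifact (see [write_schedule()]).
#'
#' Blind codes are drawn without replacement from a seeded shuffle of a
#' base-36 code space (not sequentially), so code order leaks nothing
#' about pooling order.
#'
#' @param plans list of `sampling_plan` objects.
#' @param seed integer seed for the permutation and code draw.
#' @return object of class `presentation_schedule` with fields `items`
#'   (tibble: `presentation_rank` 0-based, `blind_code`, `video_id`,
#'   `chunk_id`, `start_s`, `dur_s`) and `blind_map` (tibble:
#'   `blind_code`, `video_id`, `chunk_id`, `start_s`).
#' @export
#' @examples
#' plans <- lapply(c("a", "b"), sample_chunks, duration_s = 1800,
#'                 params = sampling_params(master_seed = 1))
#' sched <- build_presentation(plans, seed = 99)
#' nrow(sched$items)
build_presentation <- function(plans, seed) {
  if (length(plans) == 0L) stop("no plans supplied", call. = FALSE)
  stopifnot(all(vapply(plans, inherits, logical(1), "sampling_plan")))
  pooled <- do.call(rbind, lapply(plans, `[[`, "chunks"))
  key <- paste(pooled$video_id, pooled$chunk_id, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (video_id, chunk_id): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  n <- nrow(pooled)
  space <- 36L^4L  # 1,679,616 four-character codes
  if (n > space) stop("too many chunks for the blind-code space", call. = FALSE)
  perm <- with_substream(seed, "presentation-order", code = sample.int(n))
  codes <- int_to_base36(
    with_substream(seed, "blind-codes", code = sample.int(space, n)) - 1L
  )
  items <- pooled[perm, , drop = FALSE]
  items <- tibble(
    presentation_rank = seq_len(n) - 1L,
    blind_code = codes,
    video_id = items$video_id,
    chunk_id = items$chunk_id,
    start_s = items$start_s,
    dur_s = items$dur_s
  )
  structure(
    list(items = items,
         blind_map = items[, c("blind_code", "video_id", "chunk_id", "start_s")]),
    class = "presentation_schedule"
  )
}

#' Reverse the blinding of scored chunks
#'
#' Relabels a table of scores keyed by `blind_code` back to
#' `(video_id, chunk_id)` via the schedule's blind map. The relabeling
#' is bijective: no score is lost or duplicated.
#'
#' @param schedule a `presentation_schedule`.
#' @param scores data frame with a `blind_code` column plus score columns.
#' @return tibble: `video_id`, `chunk_id`, `start_s`, then the score
#'   columns, one row per input score row.
#' @export
unblind <- function(schedule, scores) {
  stopifnot(inherits(schedule, "presentation_schedule"))
  scores <- as_tibble(as.data.frame(scores, stringsAsFactors = FALSE))
  if (!"blind_code" %in% names(scores)) {
    stop("scores must have a blind_code column", call. = FALSE)
  }
  bm <- schedule$blind_map
  unknown <- setdiff(scores$blind_code, bm$blind_code)
  if (length(unknown) > 0L) {
    stop("unknown blind code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  i <- match(scores$blind_code, bm$blind_code)
  out <- cbind(bm[i, c("video_id", "chunk_id", "start_s")],
               scores[, setdiff(names(scores), "blind_code"), drop = FALSE])
  as_tibble(out)
}

#' Write / read a presentation schedule
#'
#' Two files are written: the scorer-facing schedule
#' (`presentation_rank,blind_code,dur_s` — deliberately without any
#' column from which video, subject or day could be recovered) and the
#' blind map (`blind_code,video_id,chunk_id,start_s`), which must be
#' kept away from the scorer until unblinding.
#'
#' @param schedule a `presentation_schedule`.
#' @param path scorer-facing schedule CSV path.
#' @param blind_map_path blind-map CSV path (defaults to
#'   `<path base>_blindmap.csv`).
#' @return `write_schedule`: `path`, invisibly. `read_schedule`: a
#'   `presentation_schedule` (requires both files).
#' @export
write_schedule <- function(schedule, path,
                           blind_map_path = sub("\\.csv$", "_blindmap.csv", path)) {
  stopifnot(inherits(schedule, "presentation_schedule"))
  it <- schedule$items
  writeLines(c("presentation_rank,blind_code,dur_s",
               sprintf("%d,%s,%s", it$presentation_rank, it$blind_code,
                       fmt_s(it$dur_s))),
             path, useBytes = TRUE)
  bm <- schedule$blind_map
  writeLines(c("blind_code,video_id,chunk_id,start_s",
               sprintf("%s,%s,%s,%s", bm$blind_code, bm$video_id, bm$chunk_id,
                       fmt_s(bm$start_s))),
             blind_map_path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path,
                          blind_map_path = sub("\\.csv$", "_blindmap.csv", path)) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  bm <- utils::read.csv(blind_map_path, stringsAsFactors = FALSE)
  need_sc <- c("presentation_rank", "blind_code", "dur_s")
  need_bm <- c("blind_code", "video_id", "chunk_id", "start_s")
  if (length(setdiff(need_sc, names(sc))) > 0L ||
      length(setdiff(need_bm, names(bm))) > 0L) {
    stop("schedule/blind-map file missing required columns", call. = FALSE)
  }
  n <- nrow(sc)
  if (!identical(sort(sc$presentation_rank), seq_len(n) - 1L) &&
      !identical(as.integer(sort(sc$presentation_rank)), seq_len(n) - 1L)) {
    stop("presentation ranks must be 0..N-1 with no gaps", call. = FALSE)
  }
  if (anyDuplicated(sc$blind_code) || anyDuplicated(bm$blind_code)) {
    stop("blind codes must be unique", call. = FALSE)
  }
  sc <- sc[order(sc$presentation_rank), , drop = FALSE]
  i <- match(sc$blind_code, bm$blind_code)
  if (anyNA(i)) stop("schedule blind code absent from blind map", call. = FALSE)
  items <- tibble(
    presentation_rank = as.integer(sc$presentation_rank),
    blind_code = sc$blind_code,
    video_id = bm$video_id[i],
    chunk_id = bm$chunk_id[i],
    start_s = bm$start_s[i],
    dur_s = sc$dur_s
  )
  structure(
    list(items = items,
         blind_map = items[, c("blind_code", "video_id", "chunk_id", "start_s")]),
    class = "presentation_schedule"
  )
}
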