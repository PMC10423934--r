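#' Scoring configuration
#'
#' @param cutoff_initiate_s censoring cutoff for the latency to initiate
#'   pup retrieval, seconds (default 300: a dam that has not begun
#'   retrieving by then is recorded at the cutoff, censored).
#' @param completion_horizon_s censoring horizon for the latency to
#'   complete retrieval, seconds (default 1800, the full assay length —
#'   no earlier cutoff applies to completion).
#' @param presence_rule chunk presence rule; `"any_overlap"` scores a
#'   behavior present when any positive-measure overlap (or an interior
#'   point event) falls in the chunk window.
#' @return object of class `scoring_config`.
#' @export
scoring_config <- function(cutoff_initiate_s = 300,
                           completion_horizon_s = 1800,
                           presence_rule = "any_overlap") {
  presence_rule <- match.arg(presence_rule, "any_overlap")
  stopifnot(cutoff_initiate_s > 0, completion_horizon_s > 0,
            cutoff_initiate_s <= completion_horizon_s)
  structure(
    list(cutoff_initiate_s = as.numeric(cutoff_initiate_s),
         completion_horizon_s = as.numeric(completion_horizon_s),
         presence_rule = presence_rule),
    class = "scoring_config"
  )
}

#' Score one chunk for presence/absence of each chunk-scored behavior
#'
#' A behavior is scored 1 in the half-open chunk window
#' `[start_s, start_s + dur_s)` iff some interval event of that behavior
#' overlaps the window with positive measure, or some point event falls
#' inside it. Overlapping or abutting events of one behavior behave as
#' their union, so splitting an interval into abutting sub-intervals
#' never changes a score.
#'
#' @param annotations an [annotation_set()].
#' @param chunk one chunk: a list or one-row data frame with `start_s`
#'   and `dur_s`.
#' @param ethogram an [ethogram()].
#' @param config a [scoring_config()].
#' @return named integer vector of 0/1, one per chunk-scored behavior,
#'   in ethogram order.
#' @export
score_chunk <- function(annotations, chunk, ethogram = default_ethogram(),
                        config = scoring_config()) {
  stopifnot(inherits(annotations, "annotation_set"))
  cs <- chunk$start_s[[1L]]
  ce <- cs + chunk$dur_s[[1L]]
  if (cs < 0 || ce > annotations$duration_s) {
    stop(sprintf("chunk [%g, %g) outside recording [0, %g]",
                 cs, ce, annotations$duration_s), call. = FALSE)
  }
  behaviors <- chunk_behaviors(ethogram)
  ev <- annotations$events
  out <- vapply(behaviors, function(b) {
    e <- ev[ev$behavior == b, , drop = FALSE]
    if (nrow(e) == 0L) return(0L)
    iv <- e$event_type == "interval"
    hit_iv <- any(iv & e$start_s < ce & e$stop_s > cs)
    hit_pt <- any(!iv & e$start_s >= cs & e$start_s < ce)
    as.integer(hit_iv || hit_pt)
  }, integer(1))
  out
}

#' Build the chunk-by-behavior score sheet for one recording
#'
#' Applies [score_chunk()] across every chunk of a sampling plan,
#' yielding the binary presence/absence matrix a human scorer would
#' produce for the same plan.
#'
#' @param annotations an [annotation_set()].
#' @param plan a `sampling_plan` for the same `video_id`.
#' @param ethogram an [ethogram()].
#' @param config a [scoring_config()].
#' @return object of class `score_sheet`: a tibble with `video_id`,
#'   `chunk_id`, `start_s`, `dur_s`, then one 0/1 column per
#'   chunk-scored behavior in ethogram order; one row per chunk.
#' @export
build_scoresheet <- function(annotations, plan, ethogram = default_ethogram(),
                             config = scoring_config()) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(plan, "sampling_plan"))
  if (!identical(annotations$video_id, plan$video_id)) {
    stop(sprintf("video id mismatch: annotations '%s' vs plan '%s'",
                 annotations$video_id, plan$video_id), call. = FALSE)
  }
  ch <- plan$chunks
  mat <- t(vapply(seq_len(nrow(ch)), function(i) {
    score_chunk(annotations, ch[i, ], ethogram, config)
  }, integer(length(chunk_behaviors(ethogram)))))
  colnames(mat) <- chunk_behaviors(ethogram)
  out <- cbind(ch[, c("video_id", "chunk_id", "start_s", "dur_s")],
               as.data.frame(mat, check.names = FALSE))
  out <- as_tibble(out)
  class(out) <- c("score_sheet", class(out))
  out
}

#' Tally the chunks in which a behavior was present
#'
#' The per-recording count (out of the number of chunks scored, 30 under
#' the defaults) used for group comparisons of chunk-scored behaviors.
#'
#' @param scoresheet a `score_sheet`.
#' @param behavior a chunk-scored behavior name present in the sheet.
#' @return integer count in `[0, nrow(scoresheet)]`.
#' @export
tally <- function(scoresheet, behavior) {
  stopifnot(inherits(scoresheet, "score_sheet"))
  if (!behavior %in% names(scoresheet)) {
    stop("unknown behavior in score sheet: ", behavior, call. = FALSE)
  }
  sum(scoresheet[[behavior]])
}

#' Latency to initiate pup retrieval, with censoring
#'
#' Earliest `start_s` of any "pup retrieval" event, provided it precedes
#' the cutoff; otherwise the cutoff value with the censored flag set.
#' Computed from the full event stream, not from sampled chunks.
#'
#' @param annotations an [annotation_set()].
#' @param config a [scoring_config()].
#' @return list with `latency_s` and `censored` (logical).
#' @export
latency_to_initiate <- function(annotations, config = scoring_config()) {
  stopifnot(inherits(annotations, "annotation_set"))
  ev <- annotations$events
  starts <- ev$start_s[ev$behavior == "pup retrieval"]
  cutoff <- config$cutoff_initiate_s
  if (length(starts) == 0L || min(starts) >= cutoff) {
    list(latency_s = cutoff, censored = TRUE)
  } else {
    list(latency_s = min(starts), censored = FALSE)
  }
}

#' Latency to complete pup retrieval, with censoring
#'
#' Earliest `start_s` of an "all pups retrieved and grouped" event if it
#' precedes the completion horizon; otherwise the horizon, censored. A
#' completion recorded before the first retrieval start triggers a
#' validation warning (annotation inconsistency) but the value is still
#' returned.
#'
#' @inheritParams latency_to_initiate
#' @return list with `latency_s` and `censored` (logical).
#' @export
latency_to_complete <- function(annotations, config = scoring_config()) {
  stopifnot(inherits(annotations, "annotation_set"))
  ev <- annotations$events
  comp <- ev$start_s[ev$behavior == "all pups retrieved and grouped"]
  horizon <- config$completion_horizon_s
  if (length(comp) == 0L || min(comp) >= horizon) {
    return(list(latency_s = horizon, censored = TRUE))
  }
  ret <- ev$start_s[ev$behavior == "pup retrieval"]
  if (length(ret) > 0L && min(comp) < min(ret)) {
    warning("completion annotated before first retrieval start; check events",
            call. = FALSE)
  }
  list(latency_s = min(comp), censored = FALSE)
}

#' Validate an ordinal nest score
#'
#' Nests are rated 0 (no nest attempted) through 4 (all material used,
#' high structured walls); only the integers 0..4 are accepted.
#'
#' @param value candidate score.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_nest_score <- function(value) {
  if (length(value) != 1L || is.na(value) || !is.numeric(value) ||
      value != as.integer(value) || value < 0 || value > 4) {
    stop("nest score must be an integer in 0..4, got: ",
         deparse(substitute(value)), " = ", format(value), call. = FALSE)
  }
  invisible(TRUE)
}

#' Whole-video maternal-behavior measures for one recording
#'
#' Combines both censored latencies and the observed nest score (from
#' the annotation metadata) with the subject factors, as one tidy row.
#'
#' @inheritParams latency_to_initiate
#' @return one-row tibble: `video_id`, `animal_id`, `strain`,
#'   `lactation_day`, `latency_initiate_s`, `initiate_censored`,
#'   `latency_complete_s`, `complete_censored`, `nest_score`.
#' @export
whole_video_measures <- function(annotations, config = scoring_config()) {
  li <- latency_to_initiate(annotations, config)
  lc <- latency_to_complete(annotations, config)
  tibble(
    video_id = annotations$video_id,
    animal_id = annotations$animal_id,
    strain = annotations$strain,
    lactation_day = annotations$lactation_day,
    latency_initiate_s = li$latency_s,
    initiate_censored = li$censored,
    latency_complete_s = lc$latency_s,
    complete_censored = lc$censored,
    nest_score = annotations$nest_score
  )
}

#' Write / read a score sheet CSV
#' @param scoresheet a `score_sheet`.
#' @param path file path.
#' @return `write_scoresheet`: `path` invisibly; `read_scoresheet`: a
#'   `score_sheet` tibble.
#' @export
write_scoresheet <- function(scoresheet, path) {
  stopifnot(inherits(scoresheet, "score_sheet"))
  utils::write.csv(as.data.frame(scoresheet, check.names = FALSE), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_scoresheet
#' @export
read_scoresheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- as_tibble(df)
  class(out) <- c("score_sheet", class(out))
  out
}
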