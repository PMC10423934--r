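EVENT_TYPES <- c("interval", "point")

#' Construct an annotation set
#'
#' One annotation set holds all scored behavioral events for a single
#' recording, together with the recording metadata (duration, nominal
#' frame rate) and subject factors (animal, strain, lactation day).
#' Events are either intervals, stored half-open as `[start_s, stop_s)`,
#' or point events, stored with `stop_s == start_s`. Times are seconds
#' with millisecond precision; frame indices are never stored (derive as
#' `round(t * fps)` if needed).
#'
#' @param video_id recording identifier.
#' @param duration_s recording duration in seconds.
#' @param events data frame with columns `behavior`, `event_type`
#'   (`"interval"` or `"point"`), `start_s`, `stop_s`. May have zero rows.
#' @param fps nominal frame rate (metadata only; no pixel data is touched).
#' @param animal_id,strain,lactation_day,annotator subject/session metadata.
#' @param nest_score optional observed nest score (integer 0-4) rated at
#'   assay end, or `NA` when not scored.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(video_id, duration_s, events = NULL, fps = 30,
                           animal_id = NA_character_, strain = NA_character_,
                           lactation_day = NA_integer_,
                           annotator = NA_character_,
                           nest_score = NA_integer_) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- tibble(behavior = character(), event_type = character(),
                     start_s = numeric(), stop_s = numeric())
  } else {
    events <- as_tibble(as.data.frame(events, stringsAsFactors = FALSE))
    req <- c("behavior", "event_type", "start_s", "stop_s")
    miss <- setdiff(req, names(events))
    if (length(miss) > 0L) {
      stop("events missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    events <- events[, req]
    events$behavior <- as.character(events$behavior)
    events$event_type <- as.character(events$event_type)
    events$start_s <- as.numeric(events$start_s)
    events$stop_s <- as.numeric(events$stop_s)
  }
  stopifnot(is.numeric(duration_s), length(duration_s) == 1L, duration_s > 0)
  if (!is.na(nest_score)) validate_nest_score(nest_score)
  structure(
    list(
      video_id = as.character(video_id),
      duration_s = as.numeric(duration_s),
      fps = as.numeric(fps),
      animal_id = as.character(animal_id),
      strain = as.character(strain),
      lactation_day = as.integer(lactation_day),
      annotator = as.character(annotator),
      nest_score = if (is.na(nest_score)) NA_integer_ else as.integer(nest_score),
      events = events
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %.1f s, %d events (%s, %s, LD%s)\n",
              x$video_id, x$duration_s, nrow(x$events),
              x$animal_id, x$strain, x$lactation_day))
  invisible(x)
}

#' Validate an annotation set against an ethogram
#'
#' Checks every event for: membership of its behavior in the ethogram,
#' a known event type, interval events with `start_s < stop_s`, point
#' events with `stop_s == start_s`, and all times inside
#' `[0, duration_s]`. Violations are returned as data, not raised.
#'
#' @param annotations an [annotation_set()].
#' @param ethogram an [ethogram()].
#' @return a tibble with columns `event` (row index), `rule`, `message`;
#'   zero rows iff the set is fully valid.
#' @export
validate_annotation_set <- function(annotations, ethogram) {
  stopifnot(inherits(annotations, "annotation_set"), inherits(ethogram, "ethogram"))
  ev <- annotations$events
  dur <- annotations$duration_s
  out <- list()
  add <- function(i, rule, msg) {
    out[[length(out) + 1L]] <<- tibble(event = i, rule = rule, message = msg)
  }
  for (i in seq_len(nrow(ev))) {
    b <- ev$behavior[i]; et <- ev$event_type[i]
    s <- ev$start_s[i]; e <- ev$stop_s[i]
    if (!b %in% ethogram$name) {
      add(i, "unknown_behavior", sprintf("behavior '%s' not in ethogram", b))
    }
    if (!et %in% EVENT_TYPES) {
      add(i, "unknown_event_type", sprintf("event_type '%s' invalid", et))
    } else if (et == "interval" && !(s < e)) {
      add(i, "degenerate_interval",
          sprintf("interval requires start_s < stop_s (got [%g, %g))", s, e))
    } else if (et == "point" && s != e) {
      add(i, "point_not_degenerate",
          sprintf("point event requires stop_s == start_s (got %g, %g)", s, e))
    }
    if (is.na(s) || is.na(e) || s < 0 || e < 0 || s > dur || e > dur) {
      add(i, "out_of_bounds",
          sprintf("event times [%g, %g] outside [0, %g]", s, e, dur))
    }
  }
  if (length(out) == 0L) {
    tibble(event = integer(), rule = character(), message = character())
  } else {
    do.call(rbind, out)
  }
}

ANNOT_META_KEYS <- c("video_id", "duration_s", "fps", "animal_id", "strain",
                     "lactation_day", "annotator", "nest_score")
ANNOT_COLUMNS <- c("video_id", "behavior", "event_type", "start_s", "stop_s")

fmt_s <- function(x) sprintf("%.3f", x)

#' Write an annotation set to CSV
#'
#' UTF-8, comma-separated, `.` decimal mark. Recording and subject
#' metadata are written as leading `# key=value` comment lines, followed
#' by the column header `video_id,behavior,event_type,start_s,stop_s`
#' and one row per event. Times are written with millisecond precision,
#' making write-then-read lossless for any valid set.
#'
#' @param annotations an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  a <- annotations
  meta <- c(
    video_id = a$video_id, duration_s = fmt_s(a$duration_s),
    fps = as.character(a$fps), animal_id = a$animal_id, strain = a$strain,
    lactation_day = as.character(a$lactation_day), annotator = a$annotator,
    nest_score = as.character(a$nest_score)
  )
  lines <- c(
    sprintf("# %s=%s", names(meta), unname(meta)),
    paste(ANNOT_COLUMNS, collapse = ",")
  )
  ev <- a$events
  if (nrow(ev) > 0L) {
    lines <- c(lines, sprintf("%s,%s,%s,%s,%s",
                              a$video_id, ev$behavior, ev$event_type,
                              fmt_s(ev$start_s), fmt_s(ev$stop_s)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

parse_meta_block <- function(lines) {
  meta_lines <- lines[startsWith(lines, "#")]
  kv <- sub("^#\\s*", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

num_or_na <- function(x) {
  if (is.null(x) || is.na(x) || x == "NA") NA_real_ else as.numeric(x)
}

#' Read an annotation set from CSV
#'
#' Inverse of [write_annotations_csv()]. Malformed numeric fields raise
#' a parse error citing the offending file line; a missing required
#' column raises a schema error.
#'
#' @param path input path.
#' @return an [annotation_set()].
#' @export
read_annotations_csv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  meta <- parse_meta_block(lines)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("no header row in ", path, call. = FALSE)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  miss <- setdiff(ANNOT_COLUMNS, header)
  if (length(miss) > 0L) {
    stop("annotation CSV missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n_meta <- sum(startsWith(lines, "#"))
  rows <- body[-1L]
  ev <- tibble(behavior = character(), event_type = character(),
               start_s = numeric(), stop_s = numeric())
  if (length(rows) > 0L) {
    parts <- strsplit(rows, ",", fixed = TRUE)
    idx <- stats::setNames(seq_along(header), header)
    get_num <- function(p, col, line_no) {
      v <- suppressWarnings(as.numeric(p[[idx[[col]]]]))
      if (is.na(v)) {
        stop(sprintf("line %d: non-numeric %s '%s'", line_no, col,
                     p[[idx[[col]]]]), call. = FALSE)
      }
      v
    }
    ev <- do.call(rbind, lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      line_no <- n_meta + 1L + i
      if (length(p) != length(header)) {
        stop(sprintf("line %d: expected %d fields, got %d", line_no,
                     length(header), length(p)), call. = FALSE)
      }
      tibble(behavior = p[[idx[["behavior"]]]],
             event_type = p[[idx[["event_type"]]]],
             start_s = get_num(p, "start_s", line_no),
             stop_s = get_num(p, "stop_s", line_no))
    }))
  }
  ns <- meta[["nest_score"]]
  annotation_set(
    video_id = meta[["video_id"]],
    duration_s = as.numeric(meta[["duration_s"]]),
    events = ev,
    fps = num_or_na(meta[["fps"]]),
    animal_id = meta[["animal_id"]],
    strain = meta[["strain"]],
    lactation_day = as.integer(num_or_na(meta[["lactation_day"]])),
    annotator = meta[["annotator"]],
    nest_score = if (is.null(ns) || ns == "NA") NA_integer_ else as.integer(ns)
  )
}
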