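#' Hours of video a drive can hold
#'
#' Scales a known (file size, recorded hours) pair to a drive capacity,
#' truncating to one decimal place — e.g. a half-hour 1296x972 @ 30 fps
#' recording of just under 3 GB gives 42.6 h on a 256 GB drive. The
#' result is floored, not rounded, so the estimate is conservative.
#'
#' @param drive_gb drive capacity, GB (>= 0).
#' @param file_gb size of a reference recording, GB (> 0).
#' @param file_hours duration of that reference recording, hours (> 0).
#' @return hours, truncated to one decimal.
#' @export
#' @examples
#' storage_capacity(256, 3, 0.5) # 42.6
storage_capacity <- function(drive_gb, file_gb, file_hours) {
  if (!is.numeric(file_gb) || file_gb <= 0) {
    stop("file_gb must be positive", call. = FALSE)
  }
  if (!is.numeric(file_hours) || file_hours <= 0) {
    stop("file_hours must be positive", call. = FALSE)
  }
  if (!is.numeric(drive_gb) || drive_gb < 0) {
    stop("drive_gb must be non-negative", call. = FALSE)
  }
  hours <- file_hours * drive_gb / file_gb
  floor(hours * 10 + 1e-9) / 10
}

#' Plan a repeated-recording schedule
#'
#' `repeats` contiguous half-open recording windows of `duration_s`
#' starting at `start_time` (numeric seconds or POSIXct).
#'
#' @param start_time start of the first segment.
#' @param duration_s duration of each segment, seconds (> 0).
#' @param repeats number of segments (>= 1).
#' @return tibble: `segment` (1-based), `start`, `stop`.
#' @export
recording_schedule <- function(start_time, duration_s, repeats) {
  stopifnot(duration_s > 0, repeats >= 1)
  k <- seq_len(repeats) - 1L
  tibble(segment = k + 1L,
         start = start_time + k * duration_s,
         stop = start_time + (k + 1) * duration_s)
}

#' Parse an environmental sensor log
#'
#' CSV schema: `timestamp` (ISO-8601), `temperature_c`, `humidity_pct`.
#' Timestamps must be strictly increasing.
#'
#' @param path log file path.
#' @return object of class `env_log`: tibble with `timestamp` (POSIXct),
#'   `temperature_c`, `humidity_pct`.
#' @export
parse_env_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temperature_c", "humidity_pct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("env log missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) stop("unparseable timestamp in env log", call. = FALSE)
  if (nrow(df) > 1L && any(diff(as.numeric(ts)) <= 0)) {
    stop("env log timestamps must be strictly increasing", call. = FALSE)
  }
  out <- tibble(timestamp = ts,
                temperature_c = as.numeric(df$temperature_c),
                humidity_pct = as.numeric(df$humidity_pct))
  class(out) <- c("env_log", class(out))
  out
}

#' Summary statistics of an env log over a time window
#'
#' Min/mean/max of each channel over samples with
#' `t0 <= timestamp < t1`. An empty window returns a zero-count result
#' with `NA` statistics rather than an error.
#'
#' @param log an `env_log` from [parse_env_log()].
#' @param t0,t1 window bounds (POSIXct or anything comparable to the
#'   log's timestamps), `t0 < t1`.
#' @return tibble: `channel`, `n`, `min`, `mean`, `max`.
#' @export
window_stats <- function(log, t0, t1) {
  stopifnot(inherits(log, "env_log"), t0 < t1)
  sel <- log$timestamp >= t0 & log$timestamp < t1
  stat_row <- function(channel, x) {
    if (length(x) == 0L) {
      tibble(channel = channel, n = 0L, min = NA_real_, mean = NA_real_,
             max = NA_real_)
    } else {
      tibble(channel = channel, n = length(x), min = min(x), mean = mean(x),
             max = max(x))
    }
  }
  rbind(stat_row("temperature_c", log$temperature_c[sel]),
        stat_row("humidity_pct", log$humidity_pct[sel]))
}
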