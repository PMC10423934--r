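# Shared fixtures and independent oracles, built in code at test time.

events_tbl <- function(behavior, event_type, start_s, stop_s) {
  tibble::tibble(behavior = behavior, event_type = event_type,
                 start_s = start_s, stop_s = stop_s)
}

# Random valid annotation set with times on a 0.5 s grid (so the
# grid-based scoring oracle below is exact) and millisecond-precision
# storage (so CSV round-trip is lossless).
rand_annotation_set <- function(seed, duration_s = 1800, n_events = 12) {
  withr::with_seed(seed, {
    eth <- default_ethogram()
    behaviors <- sample(chunk_behaviors(eth), n_events, replace = TRUE)
    type <- sample(c("interval", "point"), n_events, replace = TRUE,
                   prob = c(0.8, 0.2))
    start <- sample(seq(0, duration_s - 1, by = 0.5), n_events, replace = TRUE)
    len <- sample(seq(0.5, 40, by = 0.5), n_events, replace = TRUE)
    stop <- ifelse(type == "point", start, pmin(start + len, duration_s))
    annotation_set(
      video_id = sprintf("vid_%03d", seed), duration_s = duration_s,
      events = events_tbl(behaviors, type, start, stop),
      fps = 30, animal_id = sprintf("a%03d", seed),
      strain = sample(c("c57bl6", "dba2j"), 1),
      lactation_day = sample(c(1L, 3L, 5L), 1), annotator = "tester",
      nest_score = sample(0:4, 1)
    )
  })
}

# Independent presence oracle: probe the half-open chunk window on a
# fine regular grid (valid because all fixture event times sit on a
# coarser grid) instead of interval arithmetic.
oracle_score_chunk <- function(ann, chunk_start, chunk_dur, behaviors,
                               step = 0.25) {
  probes <- seq(chunk_start, chunk_start + chunk_dur - step, by = step)
  ev <- ann$events
  vapply(behaviors, function(b) {
    e <- ev[ev$behavior == b, , drop = FALSE]
    if (nrow(e) == 0) return(0L)
    hit <- FALSE
    for (i in seq_len(nrow(e))) {
      if (e$event_type[i] == "interval") {
        if (any(probes >= e$start_s[i] & probes < e$stop_s[i])) hit <- TRUE
      } else {
        if (e$start_s[i] >= chunk_start &&
            e$start_s[i] < chunk_start + chunk_dur) hit <- TRUE
      }
    }
    as.integer(hit)
  }, integer(1))
}

# Brute-force exact rank-sum oracle: enumerate every n1-subset of the
# pooled positions with utils::combn and count tail assignments directly.
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(pooled); n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  ws <- utils::combn(n, n1, function(idx) sum(r[idx]))
  eps <- 1e-9
  p_le <- mean(ws <= w_obs + eps)
  p_ge <- mean(ws >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}
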