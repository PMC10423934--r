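chunk_at <- function(start_s, dur_s = 10) list(start_s = start_s, dur_s = dur_s)

test_that("chunk presence follows half-open any-overlap semantics", {
  eth <- default_ethogram()
  ann <- annotation_set("v", 1800, events_tbl(
    behavior = c("nest building", "solo rest", "pup retrieval", "solo activity"),
    event_type = c("interval", "interval", "point", "point"),
    start_s = c(12, 20, 15, 20),
    stop_s = c(18, 25, 15, 20)
  ))
  sc <- score_chunk(ann, chunk_at(10), eth)
  expect_equal(sc[["nest building"]], 1L)     # contained interval
  expect_equal(sc[["solo rest"]], 0L)          # [20,25) misses [10,20)
  expect_equal(sc[["pup retrieval"]], 1L)      # point inside window
  expect_equal(sc[["solo activity"]], 0L)      # point on excluded boundary
  # interval ending exactly at chunk start has zero-measure overlap
  ann2 <- annotation_set("v", 1800,
                         events_tbl("nest building", "interval", 5, 10))
  expect_equal(score_chunk(ann2, chunk_at(10), eth)[["nest building"]], 0L)
  expect_error(score_chunk(ann, chunk_at(1795), eth), "outside recording")
})

test_that("score sheet covers the plan; empty and saturated columns behave", {
  eth <- default_ethogram()
  plan <- sample_chunks("v", 1800, sampling_params(master_seed = 4))
  empty <- annotation_set("v", 1800)
  sheet0 <- build_scoresheet(empty, plan, eth)
  expect_equal(nrow(sheet0), 30)
  expect_identical(names(sheet0)[-(1:4)], chunk_behaviors(eth))
  expect_true(all(as.matrix(sheet0[, -(1:4)]) == 0))
  expect_equal(tally(sheet0, "pup retrieval"), 0)

  full <- annotation_set("v", 1800,
                         events_tbl("solo activity", "interval", 0, 1800))
  sheet1 <- build_scoresheet(full, plan, eth)
  expect_true(all(sheet1[["solo activity"]] == 1))
  expect_equal(tally(sheet1, "solo activity"), 30)
  expect_error(tally(sheet1, "grooming"), "unknown behavior")
  expect_error(build_scoresheet(annotation_set("other", 1800), plan, eth),
               "mismatch")
})

test_that("chunk scoring matches an independent grid-probe oracle", {
  eth <- default_ethogram()
  behaviors <- chunk_behaviors(eth)
  for (seed in 1:100) {
    ann <- rand_annotation_set(seed, n_events = 15)
    start <- withr::with_seed(seed + 5000,
                              sample(seq(0, 1790, by = 0.5), 1))
    got <- score_chunk(ann, chunk_at(start), eth)
    want <- oracle_score_chunk(ann, start, 10, behaviors)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("scores are invariant to event order and interval splitting", {
  eth <- default_ethogram()
  plan <- sample_chunks("v", 1800, sampling_params(master_seed = 8))
  ann <- rand_annotation_set(7, n_events = 14)
  ann$video_id <- "v"
  base <- build_scoresheet(ann, plan, eth)

  perm <- withr::with_seed(2, sample.int(nrow(ann$events)))
  shuffled <- ann
  shuffled$events <- ann$events[perm, ]
  expect_equal(build_scoresheet(shuffled, plan, eth), base)

  iv <- which(ann$events$event_type == "interval" &
                ann$events$stop_s - ann$events$start_s >= 1)[1]
  e <- ann$events[iv, ]
  mid <- round((e$start_s + e$stop_s) / 2, 3)
  split <- ann
  split$events <- rbind(
    ann$events[-iv, ],
    events_tbl(e$behavior, "interval", c(e$start_s, mid), c(mid, e$stop_s))
  )
  expect_equal(build_scoresheet(split, plan, eth), base)
})

test_that("initiation latency censors at the 300 s cutoff", {
  cfg <- scoring_config()
  first <- annotation_set("v", 1800, events_tbl(
    "pup retrieval", "interval", c(45.2, 90), c(50, 95)))
  expect_equal(latency_to_initiate(first, cfg),
               list(latency_s = 45.2, censored = FALSE))

  none <- annotation_set("v", 1800)
  expect_equal(latency_to_initiate(none, cfg),
               list(latency_s = 300, censored = TRUE))

  late <- annotation_set("v", 1800,
                         events_tbl("pup retrieval", "interval", 310, 315))
  expect_equal(latency_to_initiate(late, cfg),
               list(latency_s = 300, censored = TRUE))
})

test_that("completion latency uses the assay-length horizon", {
  cfg <- scoring_config()
  done <- annotation_set("v", 1800, events_tbl(
    behavior = c("pup retrieval", "all pups retrieved and grouped"),
    event_type = "interval", start_s = c(40, 120), stop_s = c(45, 1800)))
  expect_equal(latency_to_complete(done, cfg),
               list(latency_s = 120, censored = FALSE))

  never <- annotation_set("v", 1800,
                          events_tbl("pup retrieval", "interval", 40, 45))
  expect_equal(latency_to_complete(never, cfg),
               list(latency_s = 1800, censored = TRUE))

  odd <- annotation_set("v", 1800, events_tbl(
    behavior = c("pup retrieval", "all pups retrieved and grouped"),
    event_type = "interval", start_s = c(200, 100), stop_s = c(205, 1800)))
  expect_warning(res <- latency_to_complete(odd, cfg), "before first retrieval")
  expect_equal(res$latency_s, 100)
})

test_that("latency is monotone: an earlier qualifying event never raises it", {
  cfg <- scoring_config()
  for (seed in 1:20) {
    ann <- rand_annotation_set(seed)
    before <- latency_to_initiate(ann, cfg)
    t_new <- withr::with_seed(seed + 900, round(runif(1, 0, 290), 3))
    augmented <- ann
    augmented$events <- rbind(
      ann$events, events_tbl("pup retrieval", "interval", t_new, t_new + 4))
    after <- latency_to_initiate(augmented, cfg)
    expect_lte(after$latency_s, before$latency_s)
  }
})

test_that("nest scores accept exactly the integers 0..4", {
  expect_true(validate_nest_score(4))
  expect_true(validate_nest_score(0))
  expect_error(validate_nest_score(5), "0..4")
  expect_error(validate_nest_score(-1), "0..4")
  expect_error(validate_nest_score(2.5), "0..4")
})

test_that("whole-video measures assemble one tidy row and round-trip via CSV", {
  ann <- annotation_set(
    "v", 1800,
    events_tbl(behavior = c("pup retrieval", "all pups retrieved and grouped"),
               event_type = "interval", start_s = c(33.5, 150),
               stop_s = c(38, 1800)),
    animal_id = "dam1", strain = "c57bl6", lactation_day = 3L,
    nest_score = 4L
  )
  m <- whole_video_measures(ann)
  expect_equal(m$latency_initiate_s, 33.5)
  expect_false(m$initiate_censored)
  expect_equal(m$latency_complete_s, 150)
  expect_equal(m$nest_score, 4L)
  expect_equal(m$lactation_day, 3L)

  plan <- sample_chunks("v", 1800, sampling_params(master_seed = 2))
  sheet <- build_scoresheet(ann, plan)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scoresheet(sheet, f)
  expect_equal(read_scoresheet(f), sheet)
})
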