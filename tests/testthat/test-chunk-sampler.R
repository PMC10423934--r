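test_that("piece partition covers the assay contiguously and rejects short recordings", {
  p <- sampling_params()
  w <- partition_pieces(1800, p)
  expect_equal(w$start_s, c(0, 600, 1200))
  expect_equal(w$stop_s, c(600, 1200, 1800))

  single <- partition_pieces(600, sampling_params(pieces_n = 1, piece_dur_s = 600))
  expect_equal(nrow(single), 1)
  expect_equal(c(single$start_s, single$stop_s), c(0, 600))

  expect_error(partition_pieces(1799, p), "at least 1800")
  expect_message(partition_pieces(1850, p), "trailing 50")
})

test_that("sampling params enforce the slot-capacity invariant", {
  expect_error(sampling_params(piece_dur_s = 95, chunk_dur_s = 10,
                               chunks_per_piece = 10),
               "exceeds")
  expect_silent(sampling_params(piece_dur_s = 100, chunk_dur_s = 10,
                                chunks_per_piece = 10))
})

test_that("default plan draws 10 chunks per piece, 30 total, non-overlapping", {
  plan <- sample_chunks("vid", 1800, sampling_params(master_seed = 5))
  expect_equal(nrow(plan$chunks), 30)
  expect_equal(unname(table(plan$chunks$piece_index)), rep(10L, 3),
               ignore_attr = TRUE)
  expect_silent(validate_sampling_plan(plan))
})

test_that("a piece that tiles exactly forces the full slot set", {
  p <- sampling_params(pieces_n = 1, piece_dur_s = 100, chunk_dur_s = 10,
                       chunks_per_piece = 10, master_seed = 3)
  plan <- sample_chunks("vid", 100, p)
  expect_equal(sort(plan$chunks$start_s), seq(0, 90, by = 10))
})

test_that("sampling is deterministic and per-video independent", {
  p <- sampling_params(master_seed = 42)
  a1 <- sample_chunks("vidA", 1800, p)
  a2 <- sample_chunks("vidA", 1800, p)
  expect_identical(a1$chunks, a2$chunks)
  # drawing another video does not perturb vidA's stream
  invisible(sample_chunks("vidB", 1800, p))
  a3 <- sample_chunks("vidA", 1800, p)
  expect_identical(a1$chunks, a3$chunks)
  # a different master seed gives a different draw
  b <- sample_chunks("vidA", 1800, sampling_params(master_seed = 43))
  expect_false(identical(a1$chunks$start_s, b$chunks$start_s))
})

test_that("plan invariants hold across random parameter draws", {
  for (seed in 1:25) {
    prm <- withr::with_seed(seed, {
      chunk_dur <- sample(c(5, 10, 15), 1)
      piece_dur <- sample(c(120, 300, 600), 1)
      max_chunks <- floor(piece_dur / chunk_dur)
      sampling_params(pieces_n = sample(1:4, 1), piece_dur_s = piece_dur,
                      chunks_per_piece = sample.int(max_chunks, 1),
                      chunk_dur_s = chunk_dur, master_seed = seed)
    })
    plan <- sample_chunks("v", prm$pieces_n * prm$piece_dur_s, prm)
    expect_silent(validate_sampling_plan(plan))
    expect_equal(sum(plan$chunks$dur_s),
                 prm$pieces_n * prm$chunks_per_piece * prm$chunk_dur_s)
  }
})

test_that("plan files round-trip and reject invariant violations", {
  plan <- sample_chunks("vid", 1800, sampling_params(master_seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$chunks, plan$chunks)
  expect_equal(back$params, plan$params)

  # forge an overlap: give the second chunk the first chunk's start time
  lines <- readLines(f)
  p7 <- strsplit(lines[7], ",")[[1]]
  p8 <- strsplit(lines[8], ",")[[1]]
  p8[4] <- p7[4]
  lines[8] <- paste(p8, collapse = ",")
  writeLines(lines, f)
  expect_error(read_plan(f), "overlap")
})

test_that("pooled presentation is a seeded permutation with opaque codes", {
  p <- sampling_params(master_seed = 1)
  plans <- lapply(sprintf("v%d", 1:6), sample_chunks, duration_s = 1800,
                  params = p)
  sched <- build_presentation(plans, seed = 11)
  it <- sched$items
  expect_equal(nrow(it), 180)
  expect_equal(sort(it$presentation_rank), 0:179)
  expect_false(anyDuplicated(it$blind_code) > 0)
  expect_true(all(nchar(it$blind_code) == 4))
  pooled_keys <- unlist(lapply(plans, function(pl)
    paste(pl$chunks$video_id, pl$chunks$chunk_id)))
  expect_setequal(paste(it$video_id, it$chunk_id), pooled_keys)
  # reproducible
  expect_identical(build_presentation(plans, seed = 11)$items, it)
  # single chunk degenerate case
  one <- sample_chunks("solo", 10,
                       sampling_params(pieces_n = 1, piece_dur_s = 10,
                                       chunks_per_piece = 1, chunk_dur_s = 10))
  s1 <- build_presentation(list(one), seed = 2)
  expect_equal(s1$items$presentation_rank, 0L)
  # duplicate chunk refs are refused
  expect_error(build_presentation(list(plans[[1]], plans[[1]]), seed = 3),
               "duplicate")
})

test_that("scorer-facing schedule file withholds all identifying columns", {
  plans <- lapply(c("c57_a1_ld1", "dba_a1_ld1"), sample_chunks,
                  duration_s = 1800, params = sampling_params(master_seed = 2))
  sched <- build_presentation(plans, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  bmf <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, f, bmf)
  scorer_view <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_identical(names(scorer_view),
                   c("presentation_rank", "blind_code", "dur_s"))
  # nothing recoverable: no video ids, chunk ids, or start times leak
  raw <- paste(readLines(f), collapse = "\n")
  expect_false(grepl("c57|dba|p[0-9]+_s", raw))

  back <- read_schedule(f, bmf)
  expect_equal(back$items, sched$items)
})

test_that("unblinding is the exact inverse of blinding", {
  plans <- lapply(sprintf("v%d", 1:3), sample_chunks, duration_s = 1800,
                  params = sampling_params(master_seed = 6))
  sched <- build_presentation(plans, seed = 8)
  scores <- tibble::tibble(blind_code = sched$items$blind_code,
                           present = rep_len(c(1L, 0L), nrow(sched$items)))
  un <- unblind(sched, scores)
  expect_equal(nrow(un), 90)
  key <- paste(un$video_id, un$chunk_id)
  expect_false(anyDuplicated(key) > 0)
  # scores survive untouched in input order, re-keyed bijectively
  expect_equal(un$present, scores$present)
  i <- match(scores$blind_code, sched$blind_map$blind_code)
  expect_equal(un$video_id, sched$blind_map$video_id[i])
  expect_equal(un$chunk_id, sched$blind_map$chunk_id[i])
  expect_error(unblind(sched, tibble::tibble(blind_code = "ZZZZ", present = 1)),
               "ZZZZ")
})

test_that("mean presentation rank is uniform across chunks over seeds", {
  plans <- lapply(c("a", "b"), sample_chunks, duration_s = 1800,
                  params = sampling_params(master_seed = 1))
  n <- 60
  ranks <- matrix(0, nrow = 300, ncol = n)
  for (s in 1:300) {
    it <- build_presentation(plans, seed = 1000L + s)$items
    key <- paste(it$video_id, it$chunk_id)
    ranks[s, ] <- it$presentation_rank[order(key)]
  }
  mean_rank <- colMeans(ranks)
  se <- sqrt((n^2 - 1) / 12) / sqrt(nrow(ranks))
  expect_true(all(abs(mean_rank - (n - 1) / 2) < 4 * se))
})
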