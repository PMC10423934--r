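# Fixed simulator constants (field-realistic, not fitted to any dataset):
# carrying one pup back takes a few seconds; the dam sniffs/licks a pup
# briefly before picking it up; nest-building bouts last tens of seconds.
RETRIEVAL_CARRY_S <- 4
APPROACH_S <- 2
NEST_BOUT_MEAN_S <- 30
NEST_BOUT_RATE <- 2  # Poisson mean of extra nest-building bouts per assay

#' Strain parameter set for the synthetic dam simulator
#'
#' Describes one strain's maternal-behavior phenotype generatively:
#' retrieval-initiation latency is lognormal (median
#' `exp(latency_log_median)` s), a dam fails to retrieve at all with
#' probability `p_fail_retrieve`, successive pup retrievals are separated
#' by gamma-distributed gaps, post-completion behavior alternates
#' pup-directed and solo bouts with exponential durations, and the final
#' nest score is drawn from `nest_score_probs`.
#'
#' @param name strain label.
#' @param latency_log_median log-seconds: log of the median initiation latency.
#' @param latency_sigma lognormal log-scale spread (0 gives a point mass).
#' @param p_fail_retrieve probability the dam never retrieves.
#' @param n_pups number of displaced pups to retrieve.
#' @param inter_retrieval_shape,inter_retrieval_scale gamma shape/scale of
#'   the gap (s) between consecutive retrievals.
#' @param bout_on_mean_s,bout_off_mean_s exponential mean durations (s) of
#'   post-completion pup-directed (crouching/resting with pups) and solo
#'   (activity/rest) bouts.
#' @param nest_score_probs probabilities of nest scores 0..4 (sums to 1).
#' @return object of class `strain_params`.
#' @export
strain_params <- function(name, latency_log_median, latency_sigma,
                          p_fail_retrieve, n_pups = 6L,
                          inter_retrieval_shape = 2,
                          inter_retrieval_scale = 15,
                          bout_on_mean_s = 120, bout_off_mean_s = 60,
                          nest_score_probs = c(0, 0.05, 0.15, 0.3, 0.5)) {
  stopifnot(latency_sigma >= 0,
            p_fail_retrieve >= 0, p_fail_retrieve <= 1,
            n_pups >= 1,
            inter_retrieval_shape > 0, inter_retrieval_scale > 0,
            bout_on_mean_s > 0, bout_off_mean_s > 0,
            length(nest_score_probs) == 5L, all(nest_score_probs >= 0),
            abs(sum(nest_score_probs) - 1) < 1e-9)
  structure(
    list(name = as.character(name),
         latency_log_median = latency_log_median,
         latency_sigma = latency_sigma,
         p_fail_retrieve = p_fail_retrieve,
         n_pups = as.integer(n_pups),
         inter_retrieval_shape = inter_retrieval_shape,
         inter_retrieval_scale = inter_retrieval_scale,
         bout_on_mean_s = bout_on_mean_s,
         bout_off_mean_s = bout_off_mean_s,
         nest_score_probs = nest_score_probs),
    class = "strain_params"
  )
}

#' Default strain parameter fixtures
#'
#' Two invented parameter sets whose only calibrated property is the
#' direction of the strain contrast: `c57bl6` dams initiate retrieval
#' fast, almost always complete, and build good nests; `dba2j` dams are
#' slower, often fail to retrieve, and build weaker nests. The values
#' are fixtures for testing the pipeline, not estimates of any real
#' colony.
#'
#' @return named list of two [strain_params()]: `c57bl6`, `dba2j`.
#' @export
default_strain_params <- function() {
  list(
    c57bl6 = strain_params(
      "c57bl6", latency_log_median = log(40), latency_sigma = 0.5,
      p_fail_retrieve = 0.02, n_pups = 6L,
      inter_retrieval_shape = 2, inter_retrieval_scale = 15,
      bout_on_mean_s = 120, bout_off_mean_s = 60,
      nest_score_probs = c(0, 0.02, 0.08, 0.30, 0.60)
    ),
    dba2j = strain_params(
      "dba2j", latency_log_median = log(180), latency_sigma = 0.7,
      p_fail_retrieve = 0.35, n_pups = 6L,
      inter_retrieval_shape = 2, inter_retrieval_scale = 25,
      bout_on_mean_s = 60, bout_off_mean_s = 150,
      nest_score_probs = c(0.15, 0.35, 0.30, 0.15, 0.05)
    )
  )
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_per_strain named integer vector of dams per strain (default
#'   `c(c57bl6 = 5, dba2j = 6)`).
#' @param days lactation days on which each dam is assayed (default 1, 3, 5).
#' @param assay_dur_s assay duration, seconds (default 1800).
#' @param seed master seed; each dam-day stream is derived from
#'   `(seed, strain, animal, day)` via [hash_seed()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_strain = c(c57bl6 = 5L, dba2j = 6L),
                       days = c(1L, 3L, 5L), assay_dur_s = 1800,
                       seed = 0L) {
  stopifnot(assay_dur_s > 0, length(days) >= 1)
  if (is.null(names(n_per_strain)) || any(!nzchar(names(n_per_strain)))) {
    stop("n_per_strain must be a named vector (names = strain labels)",
         call. = FALSE)
  }
  if (any(n_per_strain < 1)) {
    stop("n_per_strain must be >= 1 for every strain: ",
         paste(names(n_per_strain)[n_per_strain < 1], collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_per_strain = vapply(n_per_strain, as.integer, integer(1)),
         days = as.integer(days), assay_dur_s = as.numeric(assay_dur_s),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

r3 <- function(x) round(x, 3)

interval_rows <- function(behavior, start, stop) {
  behavior <- rep_len(behavior, length(start))
  keep <- stop > start
  tibble(behavior = behavior[keep], event_type = "interval",
         start_s = start[keep], stop_s = stop[keep])
}

#' Simulate one dam's maternal behavior assay
#'
#' Generates a full annotated event stream for one 30-min (by default)
#' maternal behavior test, plus the ground-truth record the pipeline
#' should recover. The stream contains: per-pup "pup retrieval"
#' intervals starting at the lognormal initiation latency with gamma
#' gaps (suppressed entirely with probability `p_fail_retrieve`), brief
#' "pup interaction" approach bouts before each retrieval, an "all pups
#' retrieved and grouped" / "all pups nested" state interval from the
#' completion time to assay end, alternating pup-directed
#' ("crouching over pups" / "resting with pups") and solo
#' ("solo activity" / "solo rest") bouts after completion, and
#' "nest building" bouts. All times are rounded to milliseconds and lie
#' within `[0, assay_dur_s]`.
#'
#' @param params a [strain_params()].
#' @param assay_dur_s assay length, seconds.
#' @param seed integer seed for this dam's stream.
#' @param video_id,animal_id,lactation_day,annotator metadata for the
#'   emitted [annotation_set()].
#' @param cutoff_initiate_s censoring cutoff used for the truth record's
#'   initiation flag (matches [scoring_config()]'s default).
#' @return list with `annotations` (an [annotation_set()]) and `truth`
#'   (one-row tibble: `video_id`, `strain`, `animal_id`, `lactation_day`,
#'   `latency_true_s`, `initiate_censored`, `completion_true_s`,
#'   `complete_censored`, `nest_score`).
#' @export
#' @examples
#' sim <- simulate_dam(default_strain_params()$c57bl6, seed = 1)
#' sim$truth
simulate_dam <- function(params, assay_dur_s = 1800, seed = 0L,
                         video_id = "sim", animal_id = "sim_01",
                         lactation_day = 1L, annotator = "simulator",
                         cutoff_initiate_s = 300) {
  stopifnot(inherits(params, "strain_params"))
  sim <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    fail <- stats::runif(1) < params$p_fail_retrieve
    latency <- stats::rlnorm(1, params$latency_log_median, params$latency_sigma)
    gaps <- if (params$n_pups > 1L) {
      stats::rgamma(params$n_pups - 1L, shape = params$inter_retrieval_shape,
                    scale = params$inter_retrieval_scale)
    } else numeric(0)

    events <- list()
    completion <- NA_real_
    if (!fail && latency < assay_dur_s) {
      starts <- latency + cumsum(c(0, gaps + RETRIEVAL_CARRY_S))
      starts <- starts[starts < assay_dur_s]
      stops <- pmin(starts + RETRIEVAL_CARRY_S, assay_dur_s)
      events <- c(events, list(
        interval_rows("pup retrieval", r3(starts), r3(stops)),
        interval_rows("pup interaction",
                      r3(pmax(0, starts - APPROACH_S)), r3(starts))
      ))
      if (length(starts) == params$n_pups &&
          stops[params$n_pups] < assay_dur_s) {
        completion <- stops[params$n_pups]
      }
    }
    if (!is.na(completion)) {
      events <- c(events, list(
        interval_rows(c("all pups retrieved and grouped", "all pups nested"),
                      r3(c(completion, completion)),
                      r3(c(assay_dur_s, assay_dur_s)))
      ))
      # alternating pup-directed vs solo bouts until assay end
      t <- completion
      on_phase <- TRUE
      bouts <- list()
      while (t < assay_dur_s) {
        mean_s <- if (on_phase) params$bout_on_mean_s else params$bout_off_mean_s
        dur <- stats::rexp(1, 1 / mean_s)
        beh <- if (on_phase) {
          sample(c("crouching over pups", "resting with pups"), 1L)
        } else {
          sample(c("solo activity", "solo rest"), 1L)
        }
        bouts[[length(bouts) + 1L]] <-
          interval_rows(beh, r3(t), r3(min(t + dur, assay_dur_s)))
        t <- t + dur
        on_phase <- !on_phase
      }
      events <- c(events, bouts)
    }
    n_nb <- 1L + stats::rpois(1, NEST_BOUT_RATE)
    nb_start <- stats::runif(n_nb, 0, assay_dur_s)
    nb_stop <- pmin(nb_start + stats::rexp(n_nb, 1 / NEST_BOUT_MEAN_S),
                    assay_dur_s)
    events <- c(events, list(interval_rows("nest building",
                                           r3(nb_start), r3(nb_stop))))
    nest_score <- sample(0:4, 1L, prob = params$nest_score_probs)
    list(fail = fail, latency = latency, completion = completion,
         events = do.call(rbind, events), nest_score = nest_score)
  })

  retrieved <- !sim$fail && sim$latency < assay_dur_s
  lat3 <- if (retrieved) r3(sim$latency) else NA_real_
  init_cens <- !retrieved || lat3 >= cutoff_initiate_s
  comp3 <- if (!is.na(sim$completion)) r3(sim$completion) else NA_real_
  ann <- annotation_set(
    video_id = video_id, duration_s = assay_dur_s, events = sim$events,
    fps = 30, animal_id = animal_id, strain = params$name,
    lactation_day = lactation_day, annotator = annotator,
    nest_score = sim$nest_score
  )
  truth <- tibble(
    video_id = video_id, strain = params$name, animal_id = animal_id,
    lactation_day = as.integer(lactation_day),
    latency_true_s = lat3,
    initiate_censored = init_cens,
    completion_true_s = comp3,
    complete_censored = is.na(comp3),
    nest_score = sim$nest_score
  )
  list(annotations = ann, truth = truth)
}

#' Simulate a full multi-strain, multi-day cohort
#'
#' One annotation set per dam per lactation day, each generated from an
#' independent stream derived from `(seed, strain, animal, day)` — so
#' the cohort is reproducible and insensitive to iteration order.
#'
#' @param config a [sim_config()].
#' @param params_per_strain named list of [strain_params()], one entry
#'   per name in `config$n_per_strain`.
#' @return list with `annotations` (named list of [annotation_set()],
#'   keyed by video id) and `truth` (tibble, one row per dam-day).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 3))
#' length(cohort$annotations) # (5 + 6) dams x 3 days
simulate_cohort <- function(config = sim_config(),
                            params_per_strain = default_strain_params()) {
  stopifnot(inherits(config, "sim_config"))
  miss <- setdiff(names(config$n_per_strain), names(params_per_strain))
  if (length(miss) > 0L) {
    stop("no strain_params for strain(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  anns <- list()
  truths <- list()
  for (strain in names(config$n_per_strain)) {
    sp <- params_per_strain[[strain]]
    for (a in seq_len(config$n_per_strain[[strain]])) {
      for (d in config$days) {
        vid <- sprintf("%s_a%02d_ld%d", strain, a, d)
        sim <- simulate_dam(
          sp, assay_dur_s = config$assay_dur_s,
          seed = hash_seed(config$seed, strain, a, d),
          video_id = vid, animal_id = sprintf("%s_%02d", strain, a),
          lactation_day = d
        )
        anns[[vid]] <- sim$annotations
        truths[[vid]] <- sim$truth
      }
    }
  }
  list(annotations = anns, truth = do.call(rbind, truths))
}

#' Write a simulated cohort to disk
#'
#' One annotation CSV per dam-day (schema of [write_annotations_csv()])
#' plus `truth.csv`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (vid in names(cohort$annotations)) {
    write_annotations_csv(cohort$annotations[[vid]],
                          file.path(dir, paste0(vid, ".csv")))
  }
  utils::write.csv(as.data.frame(cohort$truth), file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = TRUE)
  invisible(dir)
}

#' Whole-video measures for every recording of a cohort
#'
#' Convenience reduction: applies [whole_video_measures()] over a list
#' of annotation sets.
#'
#' @param annotations named list of [annotation_set()] (e.g.
#'   `simulate_cohort(...)$annotations`).
#' @param config a [scoring_config()].
#' @return tibble, one row per recording.
#' @export
cohort_measures <- function(annotations, config = scoring_config()) {
  do.call(rbind, lapply(annotations, whole_video_measures, config = config))
}

#' Compare pipeline output against simulator ground truth
#'
#' Joins the scored measures with the generator's truth table and
#' reports exact-agreement fractions for latency (uncensored dams),
#' censoring flags and nest scores, plus the empirical median of the
#' true latencies and the pipeline's censored fraction.
#'
#' @param truth truth tibble from [simulate_cohort()] or [simulate_dam()].
#' @param measures measures tibble from [cohort_measures()].
#' @return one-row tibble: `n_dams`, `n_uncensored`, `latency_agree`,
#'   `censor_agree`, `nest_agree`, `median_latency_truth`,
#'   `censored_fraction`.
#' @export
recover_parameters <- function(truth, measures) {
  i <- match(truth$video_id, measures$video_id)
  if (anyNA(i)) stop("measures missing some video_id in truth", call. = FALSE)
  m <- measures[i, , drop = FALSE]
  unc <- !truth$initiate_censored
  tibble(
    n_dams = nrow(truth),
    n_uncensored = sum(unc),
    latency_agree = if (any(unc)) {
      mean(m$latency_initiate_s[unc] == truth$latency_true_s[unc])
    } else NA_real_,
    censor_agree = mean(m$initiate_censored == truth$initiate_censored),
    nest_agree = mean(m$nest_score == truth$nest_score),
    median_latency_truth = stats::median(truth$latency_true_s, na.rm = TRUE),
    censored_fraction = mean(m$initiate_censored)
  )
}
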