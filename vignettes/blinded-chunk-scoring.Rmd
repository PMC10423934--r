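---
title: "Blinded chunk sampling and scoring of maternal behavior videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blinded chunk sampling and scoring of maternal behavior videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethochunk)
```

## The problem

Scoring a 30-minute home-cage video in full is slow, and because the rater
knows which animal, group and day they are watching, it invites bias.
ethochunk implements the analysis side of a chunk-sampling workflow that
addresses both problems at once:

1. **Stratify.** Each recording is partitioned into `pieces_n` contiguous
   *Pieces* (default three 10-minute pieces of a 30-minute assay).
   Behaviors such as pup retrieval are far more likely early in an assay;
   sampling an equal number of chunks from each piece prevents the random
   draw itself from introducing a temporal bias. Setting `pieces_n = 1`
   disables stratification for assays without temporal structure.
2. **Sample.** From every piece, `chunks_per_piece` short *Chunks* (default
   ten 10-second chunks) are drawn uniformly at random without replacement.
   With the defaults, 30 chunks — 5 minutes of video — represent a
   30-minute recording.
3. **Blind.** The chunks of all recordings a user wants to score together
   are pooled, permuted uniformly at random, and labeled with opaque codes.
   The scorer sees only `(presentation_rank, blind_code, dur_s)` and rates
   each chunk-scored behavior present or absent; the code-to-chunk map is a
   separate artifact withheld until unblinding.

The package consumes only video *metadata* (identifier, duration, frame
rate) and annotated event tables; no pixel data is ever read.

## Data model

An **ethogram** is the catalogue of scoreable behaviors. The stock
maternal-behavior ethogram has nine chunk-scored behaviors (rated 0/1 per
chunk: all pups retrieved and grouped; all pups nested; pup retrieval; pup
interaction; crouching over pups; resting with pups; nest building; solo
activity; solo rest) and three whole-video parameters (latency to initiate
retrieval; latency to complete retrieval; nest score 0–4).

Behavioral **events** are intervals or points. Intervals are half-open,
`[start_s, stop_s)`, so abutting events never double-count a boundary
instant; point events store `stop_s == start_s`. Times are seconds with
millisecond precision; frame indices are derived (`round(t * fps)`), never
stored, because frame rate can vary per recording. Overlapping intervals
of one behavior are permitted and behave as their union.

Subject metadata (animal, strain, lactation day) and the observed nest
score travel in the annotation CSV's `# key=value` header block rather
than per-row — there is one subject per recording in this assay, and the
nest score is a whole-video observation with no natural event encoding.

## Scoring semantics

A behavior is *present* in chunk `[s, s + d)` iff an interval event
overlaps the window with positive measure, or a point event lies inside
it. We deliberately use any-overlap rather than majority-of-chunk
presence: a human scorer watching a 10-s chunk marks a retrieval that
crosses it regardless of how briefly. Consequences that the tests
verify: scores are invariant to event order and to splitting an interval
into abutting sub-intervals, and an interval ending exactly at the chunk
start (zero-measure overlap) does not count.

The whole-video measures are computed from the *full* event stream, not
from chunks:

* **Latency to initiate** — earliest `start_s` of a "pup retrieval"
  event; if none occurs before the 300 s cutoff the value is recorded at
  300 s with a censoring flag.
* **Latency to complete** — earliest start of "all pups retrieved and
  grouped"; censored at the assay length (1800 s). No earlier cutoff is
  applied to completion: only initiation carries the 300 s convention,
  and extending it to completion would discard real completions between
  300 s and assay end.
* **Nest score** — the observed ordinal 0–4 rating; only integers 0..4
  validate.

## Group statistics

Groups are compared with the Wilcoxon rank-sum test. For the small group
sizes typical of this assay (5 vs 6 dams) the p-value is **exact**: the
null distribution of the group-1 rank sum is obtained by enumerating all
`choose(n1+n2, n1)` assignments of the observed pooled values, conditioning
on the observed (mid)ranks so ties need no correction. The enumeration is
carried out by a subset-sum dynamic program over doubled midranks, which
is arithmetically identical to brute-force enumeration; the test suite
checks it against an independent `combn`-based enumerator and against
`wilcox.test(exact = TRUE)` on untied data. The two-sided p-value is
`2 * min(P(W <= w), P(W >= w))`, capped at 1 — the convention most exact
implementations document. Beyond `enum_limit` (default 14 pooled
observations) a normal approximation with tie-corrected variance and 0.5
continuity correction takes over.

Censored latencies enter the test at their cutoff value (300 s), exactly
as they are plotted; no survival-analysis treatment is applied, keeping
the analysis faithful to how such assays are conventionally reported.
Group summaries are median and interquartile range, with quartiles by
linear interpolation of order statistics (`quantile` type 7); the
definition matters at these sample sizes and the oracle tests use the
same one. Per-stratum (per-lactation-day) p-values are reported raw,
with no multiplicity correction, mirroring common practice for this
assay.

## Reproducible randomness

All draws come from named substreams: a DJB2-style polynomial hash of
`(master_seed, labels...)` reduced mod 2^31 − 1 seeds an isolated RNG via
`withr::with_seed`. Two consequences the tests pin down: identical inputs
reproduce byte-identical plan/schedule/cohort files, and adding one more
video to a dataset never perturbs another video's chunk draw.

Chunk sampling uses a **slot grid**: each piece is tiled into
`floor(piece_dur_s / chunk_dur_s)` aligned, non-overlapping slots and
`chunks_per_piece` distinct slots are drawn. Continuous-start sampling
with rejection would also work, but the grid guarantees non-overlap by
construction, makes uniformity testable slot-by-slot, and handles the
edge case where the requested chunks exactly tile the piece. Blind codes
are fixed-length base-36 strings drawn from a seeded shuffle of the code
space — sequential codes would leak pooling order. Trailing video beyond
the piece span is excluded with a message rather than an error, since
recordings routinely overrun by a few seconds.

## The synthetic cohort generator

Because the package must be testable end-to-end without any video or
external data, `simulate_dam()` generates a full annotated assay with a
ground-truth record:

* initiation latency `L ~ lognormal(latency_log_median, latency_sigma)`,
  suppressed entirely with probability `p_fail_retrieve`;
* one retrieval interval per pup (fixed 4 s carry), separated by
  gamma-distributed gaps, preceded by brief pup-interaction approach
  bouts;
* an "all pups retrieved and grouped" / "all pups nested" state interval
  from the completion time `T` to assay end;
* post-completion alternation of pup-directed (crouching/resting with
  pups) and solo bouts with exponential durations;
* nest-building bouts, and a nest score drawn from `nest_score_probs`.

These are the simplest positive-support distributions with closed-form
medians, which is what the recovery tests need: the lognormal median is
`exp(latency_log_median)` and the censoring probability is
`p_fail + (1 - p_fail) * P(L > 300)` in closed form. The defaults
(`sim_config()`) follow the assay design: 5 dams of one strain and 6 of
the other, each assayed on lactation days 1, 3 and 5, 1800 s per assay.

The two stock strain parameter sets (`default_strain_params()`) are
*invented fixtures*, calibrated only in the direction of the contrast —
the `dba2j` set initiates retrieval more slowly, fails to retrieve more
often, and draws weaker nest scores than `c57bl6` — so that the pipeline
reproduces the qualitative strain effect in at least 95% of seeded
replicates at n = 5 vs 6. They are not estimates of any real colony, and
no numeric result from real data is claimed.

What the simulator does **not** emulate: nest quality evolving over the
assay (the nest score is drawn, not produced by the nest-building
process), lapses of the "all pups nested" state after completion,
circadian structure, pup development across days (days are i.i.d.), and
annotator noise. Passing tests therefore demonstrate the pipeline's
correctness on well-formed event streams, not robustness to messy human
annotation.

## Numerical choices and degenerate inputs

* Event times are rounded to milliseconds at generation and serialization;
  the CSV round-trip is lossless for such sets.
* `latency_sigma = 0` is honored exactly (`rlnorm` degenerates to the
  point mass), giving a deterministic latency for pinpoint tests.
* A completion annotated before the first retrieval start yields a
  warning, not an error, and the earliest completion is still returned.
* All pooled values equal makes the normal test's variance zero; p = 1 is
  returned with a warning rather than NaN.
* Storage capacity truncates (floors) to one decimal: the conservative
  direction for planning, and the convention that matches scaling a
  just-under-3-GB half-hour file to a 256 GB drive (42.6 h, not 42.7).
* The exact-size quotient behind "just under 3 GB" is unknowable; 3.0 GB
  is used with the truncation rule above.

## Validation problem sizes

The shipped tests exercise: the exact test against brute-force
enumeration on 200 random datasets with `n1 + n2 <= 10` including heavy
ties; sampler slot frequencies over 10,000 seeded plans (chi-square
goodness of fit plus familywise-corrected per-slot binomial bands — 60
simultaneous per-slot checks at an uncorrected 3-sigma level would
false-alarm ~15% of the time under a perfectly uniform sampler);
byte-identical end-to-end reruns from one master seed; and ground-truth
recovery on 500 simulated dams (exact latency/censoring/nest agreement,
censored fraction within 3 sigma of the closed form). These sizes give
the property checks comfortable statistical resolution while keeping the
default suite quick to run.

## Limitations

The package emits timecodes, not clips: extracting chunk video for a
human scorer, video playback, acquisition hardware control, and any
machine scoring are out of scope. Inter-rater reliability statistics are
not provided. The exact test is refused above the enumeration limit
rather than silently approximated; call the normal method explicitly.
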