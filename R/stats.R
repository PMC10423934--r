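#' Midranks of a pooled sample
#'
#' Standard ranks with ties sharing their average (mid) rank; ranks
#' always sum to `n(n+1)/2`. Thin wrapper over
#' `rank(ties.method = "average")`.
#'
#' @param values numeric vector.
#' @return numeric vector of midranks.
#' @export
#' @examples
#' midranks(c(10, 20, 20, 30)) # 1, 2.5, 2.5, 4
midranks <- function(values) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  rank(values, ties.method = "average")
}

new_rank_sum_result <- function(w, n1, n2, p, method) {
  u <- w - n1 * (n1 + 1) / 2
  structure(
    list(w_stat = w, u_stat = u, p_two_sided = p, method = method,
         n1 = n1, n2 = n2),
    class = "rank_sum_result"
  )
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum (%s): W = %g, U = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$w_stat, x$u_stat, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

# Exact null distribution of the group-1 rank sum, conditioning on the
# observed (mid)ranks: counts, over all C(n, n1) assignments of the pooled
# ranks to group 1, how many achieve each doubled rank sum. Subset-sum
# dynamic program over doubled ranks (midranks are multiples of 1/2, so
# doubling makes them integers).
rank_sum_null_counts <- function(doubled_ranks, n1) {
  n <- length(doubled_ranks)
  smax <- sum(sort(doubled_ranks, decreasing = TRUE)[seq_len(n1)])
  # counts[k + 1, s + 1] = number of k-subsets with doubled sum s
  counts <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (r in doubled_ranks) {
    kmax <- n1
    for (k in seq.int(kmax, 1L)) {
      src <- counts[k, seq_len(smax + 1L - r)]
      counts[k + 1L, seq.int(r + 1L, smax + 1L)] <-
        counts[k + 1L, seq.int(r + 1L, smax + 1L)] + src
    }
  }
  counts[n1 + 1L, ]
}

#' Exact Wilcoxon rank-sum test by enumeration
#'
#' Computes the permutation-exact two-sided p-value of the two-sample
#' rank-sum test by enumerating all `choose(n1 + n2, n1)` assignments of
#' the observed pooled values to group 1 (via a subset-sum dynamic
#' program over the observed midranks, which is arithmetically identical
#' to full enumeration). Ties are handled naturally because the
#' enumeration conditions on the observed values; no large-sample
#' approximation or tie correction is involved. The two-sided p-value is
#' `2 * min(P(W <= w_obs), P(W >= w_obs))`, capped at 1.
#'
#' @param x,y numeric vectors: the two group samples. Censored latencies
#'   should enter at their cutoff value.
#' @param enum_limit refuse enumeration when `n1 + n2` exceeds this
#'   (default 14); use [rank_sum_normal()] beyond it.
#' @return a `rank_sum_result` with `method = "exact_enumeration"`.
#' @export
#' @examples
#' rank_sum_exact(c(1, 2, 3), c(4, 5, 6)) # p = 0.1
rank_sum_exact <- function(x, y, enum_limit = 14L) {
  stopifnot(length(x) > 0, length(y) > 0,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n > enum_limit) {
    stop(sprintf(
      "n1 + n2 = %d exceeds the enumeration limit (%d); use rank_sum_normal()",
      n, enum_limit), call. = FALSE)
  }
  r <- midranks(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  d <- as.integer(round(2 * r))
  counts <- rank_sum_null_counts(d, n1)
  total <- choose(n, n1)
  dw <- as.integer(round(2 * w_obs))
  sums <- seq_along(counts) - 1L
  p_le <- sum(counts[sums <= dw]) / total
  p_ge <- sum(counts[sums >= dw]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  new_rank_sum_result(w_obs, n1, n2, p, "exact_enumeration")
}

#' Normal-approximation Wilcoxon rank-sum test
#'
#' Large-sample form of the rank-sum test: z-statistic from the group-1
#' rank sum with tie-corrected variance and a 0.5 continuity correction;
#' two-sided p from the normal tail. When all pooled values are equal
#' the variance is zero and p = 1 is returned with a warning.
#'
#' @inheritParams rank_sum_exact
#' @return a `rank_sum_result` with `method = "normal_tie_corrected"`.
#' @export
rank_sum_normal <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- midranks(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  tie_sizes <- table(c(x, y))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("zero variance: all pooled values are equal; p = 1", call. = FALSE)
    return(new_rank_sum_result(w, n1, n2, 1, "normal_tie_corrected"))
  }
  num <- w - mu
  z <- (num - sign(num) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_rank_sum_result(w, n1, n2, p, "normal_tie_corrected")
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7, the common default definition).
#'
#' @param values nonempty numeric vector.
#' @return list with `median`, `q1`, `q3`.
#' @export
#' @examples
#' median_iqr(1:5) # median 3, q1 2, q3 4
median_iqr <- function(values) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Stratified two-group comparison of a measure
#'
#' For each stratum (e.g. lactation day), compares the measure between
#' the two group labels (e.g. strains) with the Wilcoxon rank-sum test —
#' exact enumeration when `n1 + n2` is within the enumeration limit,
#' normal approximation otherwise — and summarizes each group by median
#' and IQR. Censored latencies are analyzed at their cutoff value; raw
#' per-stratum p-values are reported with no multiplicity correction.
#'
#' @param measures data frame of per-recording measures (one row each).
#' @param measure column name of the numeric measure to compare.
#' @param group column name of the two-level grouping factor.
#' @param stratify optional column name to stratify by; `NULL` compares
#'   the whole table at once.
#' @param enum_limit passed to [rank_sum_exact()].
#' @return tibble with one row per stratum: `stratum`, `group1`, `n1`,
#'   `median1`, `q1_1`, `q3_1`, `group2`, `n2`, `median2`, `q1_2`,
#'   `q3_2`, `w_stat`, `u_stat`, `p_two_sided`, `method`.
#' @export
compare_groups <- function(measures, measure, group, stratify = NULL,
                           enum_limit = 14L) {
  measures <- as.data.frame(measures, stringsAsFactors = FALSE)
  for (col in c(measure, group, stratify)) {
    if (!col %in% names(measures)) {
      stop("column not found in measures: ", col, call. = FALSE)
    }
  }
  strata <- if (is.null(stratify)) {
    list(`all` = measures)
  } else {
    split(measures, measures[[stratify]])
  }
  rows <- lapply(names(strata), function(s) {
    d <- strata[[s]]
    labs <- sort(unique(as.character(d[[group]])))
    if (length(labs) != 2L) {
      stop(sprintf("stratum '%s' has %d group level(s); exactly 2 required",
                   s, length(labs)), call. = FALSE)
    }
    x <- d[[measure]][d[[group]] == labs[1L]]
    y <- d[[measure]][d[[group]] == labs[2L]]
    res <- if (length(x) + length(y) <= enum_limit) {
      rank_sum_exact(x, y, enum_limit)
    } else {
      rank_sum_normal(x, y)
    }
    sx <- median_iqr(x); sy <- median_iqr(y)
    tibble(
      stratum = s,
      group1 = labs[1L], n1 = length(x),
      median1 = sx$median, q1_1 = sx$q1, q3_1 = sx$q3,
      group2 = labs[2L], n2 = length(y),
      median2 = sy$median, q1_2 = sy$q1, q3_2 = sy$q3,
      w_stat = res$w_stat, u_stat = res$u_stat,
      p_two_sided = res$p_two_sided, method = res$method
    )
  })
  do.call(rbind, rows)
}
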