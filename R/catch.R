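# Catch-trial inference: exact binomial rejection region and cue category.

#' Exact binomial rejection region around a null proportion
#'
#' Equal-tail exact construction for a two-sided binomial test of
#' `p = p0` on `n` trials: `k_lo` is the largest count with
#' `P(X <= k_lo) <= alpha/2` and `k_hi` the smallest count with
#' `P(X >= k_hi) <= alpha/2`. The null is rejected iff the observed count
#' `k <= k_lo` or `k >= k_hi`. When a tail cannot attain `alpha/2` the
#' corresponding bound is the sentinel `-1` (or `n + 1`), meaning no count
#' rejects on that side. For the design's 30 catch trials at `p0 = 0.5`,
#' `alpha = 0.05`, the region is (9, 21): 30% and 70% of trials.
#'
#' @param n Number of trials (>= 1).
#' @param p0 Null proportion.
#' @param alpha Two-sided significance level in (0, 1).
#' @return List with `k_lo`, `k_hi`, and `reject_prob`, the exact
#'   probability of rejection under the null.
#' @export
rejection_region <- function(n, p0 = 0.5, alpha = 0.05) {
  stopifnot(length(n) == 1L, n >= 1, n == as.integer(n),
            p0 > 0, p0 < 1, alpha > 0, alpha < 1)
  k <- 0:n
  lower_cdf <- stats::pbinom(k, n, p0)
  upper_tail <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)  # P(X >= k)
  lo <- k[lower_cdf <= alpha / 2]
  hi <- k[upper_tail <= alpha / 2]
  k_lo <- if (length(lo)) max(lo) else -1L
  k_hi <- if (length(hi)) min(hi) else n + 1L
  reject_prob <-
    (if (k_lo >= 0) stats::pbinom(k_lo, n, p0) else 0) +
    (if (k_hi <= n) stats::pbinom(k_hi - 1, n, p0, lower.tail = FALSE) else 0)
  list(k_lo = as.integer(k_lo), k_hi = as.integer(k_hi),
       reject_prob = reject_prob)
}

#' Classify catch-trial cue use
#'
#' A participant's count of catch-interval choices out of `n_catch` catch
#' trials is tested against the null of pure speed use (p = 0.5) with the
#' equal-tail exact region from [rejection_region()]. Counts at or below
#' the lower bound indicate the shorter-duration standard was preferred
#' (duration cue); counts at or above the upper bound indicate the
#' further-travelling catch interval was preferred (distance cue);
#' otherwise responding is consistent with speed alone. At n = 30 the
#' category edges fall at 30% and 70% of trials; at other n the category
#' follows the counts, not the percentages.
#'
#' @param k_picked Number of catch-interval choices.
#' @param n_catch Number of catch trials.
#' @param alpha Two-sided significance level.
#' @return An object of class `"catch_classification"`: `n_catch`,
#'   `k_picked`, `proportion`, `percent`, `k_lo`, `k_hi`, `category`.
#' @export
classify_cue_use <- function(k_picked, n_catch, alpha = 0.05) {
  stopifnot(length(k_picked) == 1L, length(n_catch) == 1L,
            k_picked >= 0, n_catch >= 1,
            k_picked == as.integer(k_picked))
  if (k_picked > n_catch) {
    stop("k_picked (", k_picked, ") exceeds n_catch (", n_catch, ")",
         call. = FALSE)
  }
  region <- rejection_region(n_catch, 0.5, alpha)
  category <- if (k_picked <= region$k_lo) "duration"
              else if (k_picked >= region$k_hi) "distance"
              else "speed"
  structure(
    list(n_catch = as.integer(n_catch), k_picked = as.integer(k_picked),
         proportion = k_picked / n_catch,
         percent = 100 * k_picked / n_catch,
         k_lo = region$k_lo, k_hi = region$k_hi, category = category),
    class = "catch_classification"
  )
}

#' @export
print.catch_classification <- function(x, ...) {
  cat(sprintf("Catch: %d/%d picked (%.1f%%), region (<=%d, >=%d) -> %s\n",
              x$k_picked, x$n_catch, x$percent, x$k_lo, x$k_hi, x$category))
  invisible(x)
}

#' Tabulate catch classifications for a set of trial records
#'
#' @param trials Trial records (possibly several participants/conditions)
#'   with columns `participant_id` (optional), `condition`, `is_catch`,
#'   `outcome` (1 = catch interval chosen on catch trials).
#' @param alpha Two-sided significance level.
#' @return Data frame with one row per participant x condition: `n`, `k`,
#'   `percent`, `category`.
#' @export
catch_table <- function(trials, alpha = 0.05) {
  catch <- trials[trials$is_catch, , drop = FALSE]
  if (nrow(catch) == 0L) {
    return(data.frame(participant_id = character(0),
                      condition = character(0), n = integer(0),
                      k = integer(0), percent = numeric(0),
                      category = character(0)))
  }
  if (is.null(catch$participant_id)) catch$participant_id <- "P1"
  groups <- unique(catch[, c("participant_id", "condition")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- catch[catch$participant_id == groups$participant_id[i] &
                 catch$condition == groups$condition[i], ]
    cl <- classify_cue_use(sum(sub$outcome), nrow(sub), alpha)
    data.frame(participant_id = groups$participant_id[i],
               condition = groups$condition[i],
               n = cl$n_catch, k = cl$k_picked, percent = cl$percent,
               category = cl$category)
  })
  do.call(rbind, rows)
}
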