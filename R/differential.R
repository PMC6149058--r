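# Differential enrichment between two conditions from per-region read
# counts: depth-normalised fold change gated at a threshold, significance
# by the upper tail of a Poisson with the scaled background count as its
# mean. This mirrors the count-based differential test used by common
# ChIP-seq peak callers.

#' Cumulative Poisson tail probability
#'
#' P(X >= k) for X ~ Poisson(lambda), the significance measure for an
#' observed target count against a scaled background expectation. Computed
#' via the survival function, numerically stable for lambda up to 1e6.
#'
#' @param k Observed count(s), non-negative integers.
#' @param lambda Expected count(s) under the null, > 0 (apply a pseudocount
#'   to zero backgrounds before calling).
#' @return Probabilities in (0, 1]; `k = 0` gives exactly 1.
#' @export
cumulative_poisson_p <- function(k, lambda) {
  if (any(lambda <= 0)) abort("lambda must be > 0 (apply a pseudocount first)")
  if (any(k < 0) || any(k != floor(k))) abort("k must be non-negative integers")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Call direction-specific differential regions
#'
#' For each region with read counts in two conditions, tests both
#' directions. Direction `A_over_B` scales the background count by the
#' depth ratio r = depth_a/depth_b, takes `lambda = max(count_b,
#' pseudocount) * r`, and computes the cumulative Poisson tail at
#' `k = count_a`; the depth-normalised fold change is
#' `FC = (count_a/depth_a) / (max(count_b, pseudocount)/depth_b)`.
#' `B_over_A` is the exact reciprocal. A region is called in a direction
#' iff `FC >= min_fold` and `p < max_p`; with `min_fold >= 1` the two
#' direction lists are disjoint.
#'
#' @param region_counts Tibble with `chrom`, `start`, `end` (or a
#'   `region_id` column), `count_a`, `count_b`.
#' @param depth_a,depth_b Total mapped reads per condition (> 0).
#' @param min_fold Minimum depth-normalised fold change (default 2).
#' @param max_p Cumulative-Poisson p-value cutoff (default 1e-4, applied to
#'   raw p; no multiple-testing correction).
#' @param pseudocount Added floor on the background count before scaling
#'   (default 0.5) so zero-background regions remain testable.
#' @param keep_all Return every region/direction with a `called` flag
#'   instead of only the calls.
#' @return Tibble of calls with `direction` (`A_over_B`/`B_over_A`),
#'   `fold_change`, `lambda`, `p`.
#' @export
call_differential <- function(region_counts, depth_a, depth_b,
                              min_fold = 2, max_p = 1e-4, pseudocount = 0.5,
                              keep_all = FALSE) {
  rc <- as_tibble(region_counts)
  if (!all(c("count_a", "count_b") %in% names(rc))) {
    abort("region_counts needs 'count_a' and 'count_b' columns")
  }
  if (depth_a <= 0 || depth_b <= 0) abort("depths must be > 0")
  if (min_fold < 1) abort("min_fold must be >= 1")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (nrow(rc) > 0) {
    if (any(rc$count_a < 0) || any(rc$count_b < 0) ||
        any(rc$count_a != floor(rc$count_a)) ||
        any(rc$count_b != floor(rc$count_b))) {
      abort("counts must be non-negative integers")
    }
  }
  empty <- rc[0, , drop = FALSE] |>
    mutate(direction = character(), fold_change = numeric(),
           lambda = numeric(), p = numeric(),
           called = logical())
  if (nrow(rc) == 0) {
    out <- empty
  } else {
    r <- depth_a / depth_b
    one_direction <- function(k, bg, scale, dir) {
      lam <- pmax(bg, pseudocount) * scale
      rc |>
        mutate(direction = dir,
               fold_change = k / lam,
               lambda = lam,
               p = cumulative_poisson_p(k, lam),
               called = .data$fold_change >= min_fold & .data$p < max_p)
    }
    out <- bind_rows(
      one_direction(rc$count_a, rc$count_b, r, "A_over_B"),
      one_direction(rc$count_b, rc$count_a, 1 / r, "B_over_A")
    )
  }
  if (!keep_all) {
    out <- filter(out, .data$called)
    out$called <- NULL
  }
  out
}

#' Summarise differential calls by sequence class
#'
#' Annotates differential regions against a genome partition (and optional
#' repeat catalog) and tallies each direction separately: `A_over_B` is the
#' "increased in A" set, `B_over_A` the decreased set.
#'
#' @param calls Output of [call_differential()].
#' @param partition A [build_partition()] result.
#' @param catalog Optional [repeat_catalog()].
#' @param rule Class assignment rule, see [annotate_peaks()].
#' @return Named list of two [class_tally()] objects, `A_over_B` and
#'   `B_over_A`.
#' @export
differential_class_summary <- function(calls, partition, catalog = NULL,
                                       rule = c("max_overlap", "midpoint")) {
  rule <- match.arg(rule)
  calls <- as_tibble(calls)
  classes <- unique(partition$intervals$class)
  per_dir <- function(dir) {
    sub <- filter(calls, .data$direction == dir)
    ann <- annotate_peaks(sub, partition, catalog, rule)
    tally_classes(ann, classes = classes)
  }
  list(A_over_B = per_dir("A_over_B"), B_over_A = per_dir("B_over_A"))
}
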