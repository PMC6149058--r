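# Over/under-representation statistics against genome-wide baselines.
# Throughout the package fold enrichment is f = observed/expected
# (f > 1 = over-represented); every report header restates this.

P_FLOOR <- 1e-300  # p-values below this render as "<1e-300"

#' Hypergeometric representation test
#'
#' Tests whether a category appears in a sample of peaks more or less often
#' than drawing without replacement from the genome-wide repeat universe
#' predicts: observed `k` of `n` sampled peaks in the category, against `K`
#' of `N` instances genome-wide. `p_over = P(X >= k)` and
#' `p_under = P(X <= k)` for X ~ Hypergeometric(N, K, n); fold enrichment
#' `f = (k/n) / (K/N)`.
#'
#' @param k Observed category count(s) in the sample.
#' @param n Sample size (peaks in the repeat universe).
#' @param K Category count(s) in the genome.
#' @param N Total repeats in the genome.
#' @return Tibble with `k`, `n`, `K`, `N`, `expected_prop`,
#'   `expected_count`, `fold`, `p_over`, `p_under` (both floored at
#'   1e-300).
#' @export
hypergeom_representation <- function(k, n, K, N) {
  d <- tibble(k = k, n = n, K = K, N = N)
  with(d, {
    if (any(k < 0 | n < 0 | K < 0 | N <= 0)) abort("counts must be non-negative, N > 0")
    if (any(k > n) || any(k > K)) abort("need k <= min(n, K)")
    if (any(n > N) || any(K > N)) abort("need n <= N and K <= N")
    if (any(n - k > N - K)) abort("need n - k <= N - K")
  })
  d |>
    mutate(
      expected_prop = .data$K / .data$N,
      expected_count = .data$n * .data$expected_prop,
      fold = ifelse(.data$n == 0, NA_real_,
                    (.data$k / .data$n) / .data$expected_prop),
      p_over = pmax(phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                           lower.tail = FALSE), P_FLOOR),
      p_under = pmax(phyper(.data$k, .data$K, .data$N - .data$K, .data$n),
                     P_FLOOR)
    )
}

#' Repeat-category representation of a peak set
#'
#' Applies [hypergeom_representation()] to every category of a repeat
#' catalog, taking the sample to be the peaks overlapping any repeat, with
#' Benjamini-Hochberg adjustment across the category family (one family per
#' report).
#'
#' @param tally A [class_tally()] (its `by_repeat` slot supplies k), or a
#'   tibble with `category` and `n` columns of per-category peak counts.
#' @param catalog The genome-wide [repeat_catalog()].
#' @return Tibble with one row per catalog category: counts, fold,
#'   `p_over`, `p_under`, `q_over`, `q_under` and a `direction` flag
#'   (`over`/`under`/`ns` at q < 0.05).
#' @export
repeat_representation <- function(tally, catalog) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  counts <- if (inherits(tally, "class_tally")) tally$by_repeat else as_tibble(tally)
  if (!all(c("category", "n") %in% names(counts))) {
    abort("need per-category counts with 'category' and 'n' columns")
  }
  fam <- catalog$category_counts |>
    left_join(counts, by = "category") |>
    mutate(k = dplyr::coalesce(as.numeric(.data$n), 0)) |>
    select("category", "k", "K")
  n_sample <- sum(fam$k)
  res <- hypergeom_representation(fam$k, n_sample, fam$K, catalog$total)
  out <- bind_cols(fam["category"], res) |>
    mutate(q_over = benjamini_hochberg(.data$p_over),
           q_under = benjamini_hochberg(.data$p_under),
           direction = dplyr::case_when(
             .data$q_over < 0.05 & .data$fold > 1 ~ "over",
             .data$q_under < 0.05 & .data$fold < 1 ~ "under",
             TRUE ~ "ns"
           ))
  out
}

#' Chi-square genome-class representation test
#'
#' One-degree-of-freedom goodness of fit comparing the observed number of
#' peaks in a class, `O_c` of `T` total peaks, with the expectation from the
#' class's genome occupancy fraction `g_c`: expected counts `T * g_c`
#' in-class and `T * (1 - g_c)` outside. Two-sided p; fold
#' `f = (O_c / T) / g_c`. No continuity correction by default.
#'
#' @param observed Observed peak count(s) per class, `O_c`.
#' @param total Total peaks `T` (> 0).
#' @param genome_fraction Genome occupancy fraction(s) `g_c` in (0, 1).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return Tibble with `observed`, `total`, `expected_prop`,
#'   `expected_count`, `fold`, `statistic`, `p_value`.
#' @export
chisq_class_representation <- function(observed, total, genome_fraction,
                                       correct = FALSE) {
  if (any(total <= 0)) abort("total peak count must be > 0")
  if (any(observed < 0) || any(observed > total)) abort("need 0 <= observed <= total")
  if (any(genome_fraction <= 0) || any(genome_fraction >= 1)) {
    abort("genome fraction must be strictly between 0 and 1")
  }
  e_in <- total * genome_fraction
  e_out <- total * (1 - genome_fraction)
  d_in <- abs(observed - e_in)
  d_out <- abs((total - observed) - e_out)
  if (correct) {
    d_in <- pmax(d_in - 0.5, 0)
    d_out <- pmax(d_out - 0.5, 0)
  }
  stat <- d_in^2 / e_in + d_out^2 / e_out
  tibble(
    observed = observed, total = total,
    expected_prop = genome_fraction,
    expected_count = e_in,
    fold = (observed / total) / genome_fraction,
    statistic = stat,
    p_value = pmax(pchisq(stat, df = 1, lower.tail = FALSE), P_FLOOR)
  )
}

#' Genome-class representation of a peak tally
#'
#' Runs [chisq_class_representation()] for every class of a partition
#' against its occupancy baseline, with Benjamini-Hochberg adjustment
#' across the class family.
#'
#' @param tally A [class_tally()] or tibble with `class` and `n` columns.
#' @param partition A [build_partition()] result supplying `g_c`.
#' @param correct Yates continuity correction flag.
#' @return Tibble with one row per class: counts, fold, `statistic`,
#'   `p_value`, `q` and a `direction` flag.
#' @export
class_representation <- function(tally, partition, correct = FALSE) {
  stopifnot(inherits(partition, "genome_partition"))
  counts <- if (inherits(tally, "class_tally")) tally$by_class else as_tibble(tally)
  if (!all(c("class", "n") %in% names(counts))) {
    abort("need per-class counts with 'class' and 'n' columns")
  }
  fam <- partition$occupancy |>
    filter(.data$fraction > 0, .data$fraction < 1) |>
    left_join(counts, by = "class") |>
    mutate(n = dplyr::coalesce(as.numeric(.data$n), 0))
  total <- sum(fam$n)
  if (total == 0) abort("no peaks to test (T = 0)")
  res <- chisq_class_representation(fam$n, total, fam$fraction,
                                    correct = correct)
  bind_cols(fam["class"], res) |>
    mutate(q = benjamini_hochberg(.data$p_value),
           direction = dplyr::case_when(
             .data$q < 0.05 & .data$fold > 1 ~ "over",
             .data$q < 0.05 & .data$fold < 1 ~ "under",
             TRUE ~ "ns"
           ))
}

#' Fisher exact test on a 2x2 table
#'
#' Conditional odds ratio and two-sided p computed by summing
#' hypergeometric probabilities no larger than that of the observed table
#' (the standard exact two-sided rule). Tables with a zero margin are
#' degenerate: p = 1 and an undefined odds ratio, flagged.
#'
#' @param a,b,c,d Non-negative integer cells, row-wise: `(a, b)` /
#'   `(c, d)`.
#' @return Tibble with `odds_ratio` (conditional MLE; `NA` when a margin is
#'   zero), `p_value`, `degenerate`.
#' @export
fisher_two_by_two <- function(a, b, c, d) {
  cells <- cbind(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("cells must be non-negative integers")
  }
  one <- function(a, b, c, d) {
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
      return(c(or = NA_real_, p = 1, degenerate = 1))
    }
    ft <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
    c(or = unname(ft$estimate), p = ft$p.value, degenerate = 0)
  }
  res <- t(mapply(one, cells[, 1], cells[, 2], cells[, 3], cells[, 4]))
  tibble(odds_ratio = res[, "or"],
         p_value = res[, "p"],
         degenerate = res[, "degenerate"] == 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; values are clipped at 1,
#' monotone non-decreasing in sorted order, and returned in input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Transcript class enrichment between two conditions
#'
#' Given per-class transcript (or read) counts in two conditions, tests
#' each class against the rest with a 2x2 Fisher exact test and reports the
#' relative proportion ratio `fold = (count_a/total_a) / (count_b/total_b)`
#' with Benjamini-Hochberg adjustment across classes. A fold of 1 is no
#' enrichment relative to a random distribution of reads over classes.
#'
#' @param counts Tibble with `class`, `count_a`, `count_b` columns (at
#'   least two classes).
#' @return Tibble with one row per class: counts, `fold`, `odds_ratio`,
#'   `p_value`, `q`.
#' @export
transcript_class_enrichment <- function(counts) {
  counts <- as_tibble(counts)
  if (!all(c("class", "count_a", "count_b") %in% names(counts))) {
    abort("counts needs 'class', 'count_a', 'count_b' columns")
  }
  if (nrow(counts) < 2) abort("need at least two classes")
  ta <- sum(counts$count_a)
  tb <- sum(counts$count_b)
  if (ta == 0 || tb == 0) abort("each condition needs a positive total")
  ft <- fisher_two_by_two(counts$count_a, ta - counts$count_a,
                          counts$count_b, tb - counts$count_b)
  counts |>
    mutate(fold = (.data$count_a / ta) / (.data$count_b / tb),
           odds_ratio = ft$odds_ratio,
           p_value = ft$p_value,
           q = benjamini_hochberg(ft$p_value))
}

#' Format a p-value for reports
#'
#' Values at or below the 1e-300 floor render as `"<1e-300"`.
#'
#' @param p Numeric p-values.
#' @param digits Significant digits.
#' @return Character vector.
#' @export
format_pvalue <- function(p, digits = 3) {
  ifelse(p <= P_FLOOR, "<1e-300", as.character(signif(p, digits)))
}
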