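# Peak annotation: each peak receives exactly one sequence class and at
# most one repeat category, so class tallies are mutually exclusive and sum
# to the number of peaks.

#' Annotate peaks with sequence class and repeat category
#'
#' Assigns every peak one sequence class from a genome partition and, when a
#' repeat catalog is given, at most one repeat category.
#'
#' Class assignment rules:
#' * `max_overlap` (default): the class with the most overlapping bp wins;
#'   ties break by partition priority order (intergenic last).
#' * `midpoint`: the class containing `floor((start + end) / 2)`.
#'
#' Repeat assignment always uses greatest bp overlap, with ties broken by
#' category name order; peaks touching no repeat get `NA`.
#'
#' @param peaks Tibble of peaks (`chrom`, `start`, `end`, optionally
#'   `peak_id`).
#' @param partition A [build_partition()] result covering the peaks'
#'   chromosomes.
#' @param catalog Optional [repeat_catalog()].
#' @param rule `"max_overlap"` or `"midpoint"`.
#' @return The input tibble with `assigned_class` and (when `catalog` is
#'   given) `repeat_category` columns added.
#' @export
annotate_peaks <- function(peaks, partition, catalog = NULL,
                           rule = c("max_overlap", "midpoint")) {
  rule <- match.arg(rule)
  stopifnot(inherits(partition, "genome_partition"))
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) {
    peaks$assigned_class <- character()
    if (!is.null(catalog)) peaks$repeat_category <- character()
    return(peaks)
  }
  validate_intervals(peaks, "peaks")
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- paste0("peak_", seq_len(nrow(peaks)))
  }
  missing_chrom <- setdiff(peaks$chrom, partition$chrom_sizes$chrom)
  if (length(missing_chrom) > 0) {
    abort(sprintf("peak chromosome(s) absent from partition: %s",
                  paste(missing_chrom, collapse = ", ")))
  }

  if (rule == "midpoint") {
    mid <- floor((as.numeric(peaks$start) + as.numeric(peaks$end)) / 2)
    peaks$assigned_class <- lookup_class(partition, peaks$chrom, mid)
  } else {
    peaks$assigned_class <- max_overlap_label(
      peaks, partition$intervals, partition$intervals$class,
      rank = class_rank(unique(partition$intervals$class), partition$priority),
      labels_universe = unique(partition$intervals$class)
    )
  }

  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "repeat_catalog"))
    if (nrow(catalog$instances) == 0) {
      peaks$repeat_category <- NA_character_
    } else {
      cats <- sort(unique(catalog$instances$category))
      peaks$repeat_category <- max_overlap_label(
        peaks, catalog$instances, catalog$instances$category,
        rank = match(cats, cats), labels_universe = cats
      )
    }
  }
  peaks
}

# For each peak, the label of the subject intervals with the greatest total
# overlapping bp; ties resolved by the supplied label rank (lower wins).
# Peaks with no overlap get NA.
max_overlap_label <- function(peaks, subject, subject_labels, rank,
                              labels_universe) {
  pk_gr <- gr_from_tbl(peaks)
  sb_gr <- gr_from_tbl(subject)
  hits <- GenomicRanges::findOverlaps(pk_gr, sb_gr)
  if (length(hits) == 0) return(rep(NA_character_, nrow(peaks)))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(pk_gr[q], sb_gr[s]))
  lab <- subject_labels[s]
  d <- tibble(peak = q, label = lab, ov = ov) |>
    group_by(.data$peak, .data$label) |>
    summarise(ov = sum(.data$ov), .groups = "drop") |>
    mutate(rank = rank[match(.data$label, labels_universe)]) |>
    group_by(.data$peak) |>
    arrange(dplyr::desc(.data$ov), .data$rank, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  out <- rep(NA_character_, nrow(peaks))
  out[d$peak] <- d$label
  out
}

#' Construct a class tally
#'
#' Low-level constructor used both by [tally_classes()] and when working
#' directly from published per-class counts.
#'
#' @param by_class Tibble with `class` and `n` columns.
#' @param by_repeat Optional tibble with `category` and `n` columns (counts
#'   of peaks whose best overlap is each repeat category).
#' @return A `class_tally` object: list with `by_class`, `by_repeat`,
#'   `total` (number of peaks) and `n_with_repeat`.
#' @export
class_tally <- function(by_class, by_repeat = NULL) {
  by_class <- as_tibble(by_class)
  stopifnot(all(c("class", "n") %in% names(by_class)),
            all(by_class$n >= 0), all(by_class$n == floor(by_class$n)))
  if (is.null(by_repeat)) {
    by_repeat <- tibble(category = character(), n = integer())
  } else {
    by_repeat <- as_tibble(by_repeat)
    stopifnot(all(c("category", "n") %in% names(by_repeat)),
              all(by_repeat$n >= 0))
  }
  total <- sum(by_class$n)
  n_with_repeat <- sum(by_repeat$n)
  if (n_with_repeat > total) abort("repeat-overlapping peaks exceed total peaks")
  structure(
    list(by_class = by_class, by_repeat = by_repeat,
         total = total, n_with_repeat = n_with_repeat),
    class = "class_tally"
  )
}

#' Tally peak class and repeat composition
#'
#' Counts annotated peaks per sequence class (every peak contributes to
#' exactly one class) and per repeat category (over peaks overlapping any
#' repeat). Counts peaks, not bp; duplicated peaks are counted as supplied,
#' never merged.
#'
#' @param peaks Annotated peak tibble from [annotate_peaks()] (needs
#'   `assigned_class`; uses `repeat_category` when present).
#' @param classes Optional class universe to zero-fill (defaults to the
#'   classes observed).
#' @return A [class_tally()] object.
#' @export
tally_classes <- function(peaks, classes = NULL) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) > 0 && !"assigned_class" %in% names(peaks)) {
    abort("peaks must be annotated first (missing 'assigned_class')")
  }
  by_class <- if (nrow(peaks) == 0) {
    tibble(class = character(), n = integer())
  } else {
    count(peaks, class = .data$assigned_class, name = "n")
  }
  if (!is.null(classes)) {
    by_class <- tibble(class = classes) |>
      left_join(by_class, by = "class") |>
      mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  by_repeat <- if ("repeat_category" %in% names(peaks)) {
    peaks |>
      filter(!is.na(.data$repeat_category)) |>
      count(category = .data$repeat_category, name = "n")
  } else {
    NULL
  }
  class_tally(by_class, by_repeat)
}

#' @export
print.class_tally <- function(x, ...) {
  cat(sprintf("<class_tally> %d peaks (%d overlapping a repeat)\n",
              x$total, x$n_with_repeat))
  print(x$by_class)
  if (nrow(x$by_repeat) > 0) print(x$by_repeat)
  invisible(x)
}
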