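# broom-style tidiers so pipeline objects drop into dplyr/ggplot2 work.

#' Tidy a genome partition
#'
#' @param x A `genome_partition`.
#' @param ... Unused.
#' @return The occupancy tibble: `class`, `occupancy_bp`, `fraction`.
#' @export
tidy.genome_partition <- function(x, ...) x$occupancy

#' One-row summary of a genome partition
#'
#' @param x A `genome_partition`.
#' @param ... Unused.
#' @return Tibble with `n_chroms`, `n_classes`, `n_intervals`, `total_bp`.
#' @export
glance.genome_partition <- function(x, ...) {
  tibble(n_chroms = nrow(x$chrom_sizes),
         n_classes = nrow(x$occupancy),
         n_intervals = nrow(x$intervals),
         total_bp = x$total_bp)
}

#' Tidy a class tally
#'
#' @param x A `class_tally`.
#' @param ... Unused.
#' @return Long tibble with `type` (`"class"`/`"repeat"`), `label`, `n`.
#' @export
tidy.class_tally <- function(x, ...) {
  bind_rows(
    mutate(rename(x$by_class, label = "class"), type = "class"),
    mutate(rename(x$by_repeat, label = "category"), type = "repeat")
  )[c("type", "label", "n")]
}

#' One-row summary of a class tally
#'
#' @param x A `class_tally`.
#' @param ... Unused.
#' @return Tibble with `total` and `n_with_repeat`.
#' @export
glance.class_tally <- function(x, ...) {
  tibble(total = x$total, n_with_repeat = x$n_with_repeat)
}

#' Tidy a repeat catalog
#'
#' @param x A `repeat_catalog`.
#' @param ... Unused.
#' @return The category-count tibble (`category`, `K`).
#' @export
tidy.repeat_catalog <- function(x, ...) x$category_counts

#' One-row summary of a repeat catalog
#'
#' @param x A `repeat_catalog`.
#' @param ... Unused.
#' @return Tibble with `n_categories` and `total` (N).
#' @export
glance.repeat_catalog <- function(x, ...) {
  tibble(n_categories = nrow(x$category_counts), total = x$total)
}
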