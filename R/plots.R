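# ggplot2 views of the main result types.

#' Plot genome class occupancy
#'
#' @param object A `genome_partition`.
#' @param ... Unused.
#' @return A ggplot: occupancy fraction per class.
#' @export
autoplot.genome_partition <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$fraction),
    y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "genome fraction (g_c)",
                  title = "Genome class occupancy") +
    ggplot2::theme_minimal()
}

#' Plot a peak class tally
#'
#' @param object A `class_tally`.
#' @param ... Unused.
#' @return A ggplot: peak counts per class (and repeat category if
#'   tallied).
#' @export
autoplot.class_tally <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~type, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "peaks",
                  title = "Peak composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot representation results
#'
#' Fold enrichment per category/class with the no-enrichment line at 1
#' dotted; points are coloured by the adjusted-significance direction
#' flag.
#'
#' @param rep_tbl Output of [repeat_representation()],
#'   [class_representation()] or [transcript_class_enrichment()].
#' @return A ggplot.
#' @export
plot_representation <- function(rep_tbl) {
  rep_tbl <- as_tibble(rep_tbl)
  label_col <- intersect(c("category", "class"), names(rep_tbl))[1]
  if (!"direction" %in% names(rep_tbl)) {
    rep_tbl$direction <- ifelse(rep_tbl$q < 0.05,
                                ifelse(rep_tbl$fold > 1, "over", "under"),
                                "ns")
  }
  ggplot2::ggplot(rep_tbl, ggplot2::aes(
    x = stats::reorder(.data[[label_col]], -.data$fold),
    y = .data$fold, colour = .data$direction)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(over = "firebrick",
                                            under = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = NULL, y = "fold enrichment (observed/expected)",
                  title = "Representation vs genome baseline") +
    ggplot2::theme_minimal()
}

#' Plot differential calls
#'
#' Depth-normalised fold change against cumulative-Poisson significance,
#' split by direction.
#'
#' @param calls Output of [call_differential()] (use `keep_all = TRUE` to
#'   show uncalled regions too).
#' @return A ggplot.
#' @export
plot_differential <- function(calls) {
  calls <- as_tibble(calls)
  ggplot2::ggplot(calls, ggplot2::aes(
    x = log2(.data$fold_change), y = -log10(pmax(.data$p, 1e-300)),
    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log2 fold change (depth-normalised)",
                  y = "-log10 cumulative Poisson p",
                  title = "Differential regions") +
    ggplot2::theme_minimal()
}
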