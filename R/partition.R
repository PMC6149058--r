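# Genome class partition: resolve possibly-overlapping class interval sets
# into a disjoint assignment of every base to exactly one sequence class,
# with the intergenic residual, and compute the occupancy baselines
# (g_c = class bp / total annotated genome size G) that the chi-square
# representation test uses as expectations.

#' Default sequence-class priority
#'
#' When input class sets overlap, the earlier class in this list claims the
#' shared bases. Mirrors the feature hierarchy commonly used by annotation
#' tools (promoter before transcript parts before intron); intergenic is
#' always the residual and never appears here.
#'
#' @return Character vector of class labels in priority order.
#' @export
class_priority <- function() {
  c("promoter", "TTS", "exon", "5UTR", "3UTR", "CpG_island",
    "small_RNA", "tRNA", "rRNA", "intron")
}

#' Build a disjoint genome class partition
#'
#' Takes per-class interval sets (which may overlap within and between
#' classes), merges each class, resolves inter-class overlaps by priority
#' (earlier class wins), and assigns every remaining base to the
#' `intergenic` residual, so that every base of every chromosome belongs to
#' exactly one class.
#'
#' @param class_intervals Either a tibble with columns `chrom`, `start`,
#'   `end`, `class`, or a named list of interval tibbles (names = class
#'   labels). `intergenic` must not be supplied; it is derived.
#' @param chrom_sizes Tibble with `chrom` and `length` (bp) columns; the sum
#'   of lengths is the total annotated genome size G.
#' @param priority Character vector giving the class priority order; every
#'   supplied class must appear in it.
#' @return A `genome_partition` object: list with `intervals` (disjoint
#'   tibble of `chrom`, `start`, `end`, `class`), `occupancy` (tibble of
#'   `class`, `occupancy_bp`, `fraction`), `total_bp` (G), `priority`,
#'   `chrom_sizes`.
#' @export
build_partition <- function(class_intervals, chrom_sizes,
                            priority = class_priority()) {
  if (is.list(class_intervals) && !is.data.frame(class_intervals)) {
    if (is.null(names(class_intervals)) || any(!nzchar(names(class_intervals)))) {
      abort("class_intervals list must be named by class label")
    }
    class_intervals <- bind_rows(
      purrr::imap(class_intervals, function(df, cls) {
        df <- as_tibble(df)
        df$class <- cls
        df[c("chrom", "start", "end", "class")]
      })
    )
  }
  class_intervals <- as_tibble(class_intervals)
  if (!"class" %in% names(class_intervals)) {
    abort("class_intervals needs a 'class' column")
  }
  validate_intervals(class_intervals, "class intervals")
  chrom_sizes <- as_tibble(chrom_sizes)
  if (!all(c("chrom", "length") %in% names(chrom_sizes))) {
    abort("chrom_sizes needs 'chrom' and 'length' columns")
  }
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicated chromosome in chrom_sizes")

  classes <- unique(class_intervals$class)
  if ("intergenic" %in% classes) {
    abort("'intergenic' is the residual class and must not be supplied")
  }
  unknown <- setdiff(classes, priority)
  if (length(unknown) > 0) {
    abort(sprintf("class(es) not in priority order: %s",
                  paste(unknown, collapse = ", ")))
  }
  missing_chrom <- setdiff(class_intervals$chrom, chrom_sizes$chrom)
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome(s) absent from chrom_sizes: %s",
                  paste(missing_chrom, collapse = ", ")))
  }
  lens <- chrom_sizes$length[match(class_intervals$chrom, chrom_sizes$chrom)]
  over <- which(class_intervals$end > lens)
  if (length(over) > 0) {
    abort(sprintf(
      "interval %s:[%d,%d) exceeds chromosome length %d",
      class_intervals$chrom[over[1]], class_intervals$start[over[1]],
      class_intervals$end[over[1]], lens[over[1]]))
  }

  seqlens <- stats::setNames(as.integer(chrom_sizes$length), chrom_sizes$chrom)
  genome_gr <- GenomicRanges::GRanges(
    seqnames = chrom_sizes$chrom,
    ranges = IRanges::IRanges(start = 1L, end = as.integer(chrom_sizes$length)),
    seqlengths = seqlens
  )
  empty_gr <- GenomicRanges::GRanges(seqlengths = seqlens)

  ordered_classes <- intersect(priority, classes)
  claimed <- empty_gr
  pieces <- list()
  for (cls in ordered_classes) {
    gr <- gr_from_tbl(class_intervals[class_intervals$class == cls, ], seqlens)
    gr <- GenomicRanges::reduce(gr)
    gr <- GenomicRanges::setdiff(gr, claimed)   # earlier classes win
    claimed <- GenomicRanges::reduce(c(claimed, gr))
    tb <- tbl_from_gr(gr)
    tb$class <- cls
    pieces[[cls]] <- tb
  }
  intergenic <- tbl_from_gr(GenomicRanges::setdiff(genome_gr, claimed))
  intergenic$class <- "intergenic"
  pieces[["intergenic"]] <- intergenic

  intervals <- bind_rows(pieces) |> arrange(.data$chrom, .data$start)
  G <- sum(as.numeric(chrom_sizes$length))
  all_classes <- c(ordered_classes, "intergenic")
  occupancy <- intervals |>
    mutate(width = as.numeric(.data$end) - as.numeric(.data$start)) |>
    group_by(.data$class) |>
    summarise(occupancy_bp = sum(.data$width), .groups = "drop")
  occupancy <- tibble(class = all_classes) |>
    left_join(occupancy, by = "class") |>
    mutate(occupancy_bp = dplyr::coalesce(.data$occupancy_bp, 0),
           fraction = .data$occupancy_bp / G)
  stopifnot(abs(sum(occupancy$occupancy_bp) - G) < 0.5)

  structure(
    list(intervals = intervals, occupancy = occupancy, total_bp = G,
         priority = priority, chrom_sizes = chrom_sizes),
    class = "genome_partition"
  )
}

#' @export
print.genome_partition <- function(x, ...) {
  cat(sprintf("<genome_partition> %d chromosome(s), G = %s bp, %d classes\n",
              nrow(x$chrom_sizes), format(x$total_bp, big.mark = ","),
              nrow(x$occupancy)))
  print(x$occupancy)
  invisible(x)
}

# rank used for priority tie-breaks: priority order, intergenic last
class_rank <- function(cls, priority) {
  match(cls, c(priority, "intergenic"))
}

#' Look up the class of single positions
#'
#' @param partition A [build_partition()] result.
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Character vector of class labels.
#' @export
lookup_class <- function(partition, chrom, pos) {
  stopifnot(inherits(partition, "genome_partition"))
  pts <- tibble(chrom = chrom, start = as.integer(pos),
                end = as.integer(pos) + 1L)
  validate_intervals(pts, "positions")
  hits <- GenomicRanges::findOverlaps(gr_from_tbl(pts),
                                      gr_from_tbl(partition$intervals))
  out <- rep(NA_character_, nrow(pts))
  out[S4Vectors::queryHits(hits)] <-
    partition$intervals$class[S4Vectors::subjectHits(hits)]
  out
}

#' Genome class occupancy report
#'
#' One row per class with its bp occupancy, the total annotated genome size
#' G, the fraction g_c = occupancy/G and the percentage rendered at two
#' decimals (the scale used when quoting genome composition).
#'
#' @param x A `genome_partition`, or a data frame with `class` and
#'   `occupancy_bp` columns (e.g. published occupancy figures).
#' @param total_bp Total genome size G; defaults to the partition's G or to
#'   `sum(occupancy_bp)` for data-frame input.
#' @return Tibble with `class`, `occupancy_bp`, `total_bp`, `fraction`,
#'   `percent`, `percent_label`.
#' @export
class_occupancy_report <- function(x, total_bp = NULL) {
  if (inherits(x, "genome_partition")) {
    occ <- x$occupancy[c("class", "occupancy_bp")]
    G <- x$total_bp
  } else {
    occ <- as_tibble(x)
    if (!all(c("class", "occupancy_bp") %in% names(occ))) {
      abort("need 'class' and 'occupancy_bp' columns")
    }
    G <- total_bp %||% sum(as.numeric(occ$occupancy_bp))
  }
  if (G <= 0) abort("total genome size must be positive")
  out <- occ |>
    mutate(total_bp = G,
           fraction = as.numeric(.data$occupancy_bp) / G,
           percent = 100 * .data$fraction,
           percent_label = sprintf("%.2f%%", .data$percent))
  if (abs(sum(out$fraction) - 1) > 1e-9 && is.null(total_bp) &&
      inherits(x, "genome_partition")) {
    abort("partition fractions do not sum to 1")
  }
  out
}
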