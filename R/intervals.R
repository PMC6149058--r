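# Interval plumbing. All coordinates inside the package are 0-based
# half-open [start, end); conversion to the 1-based inclusive convention
# GenomicRanges uses happens only at these two boundaries.

gr_from_tbl <- function(df, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(
      start = as.integer(df$start) + 1L,
      end = as.integer(df$end)
    ),
    seqlengths = if (!is.null(seqlevels)) seqlevels else NULL
  )
}

tbl_from_gr <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Validate an interval table
#'
#' Checks that a data frame carries `chrom`, `start`, `end` columns obeying
#' the half-open convention: integer coordinates with `0 <= start < end` and
#' non-empty chromosome names.
#'
#' @param df A data frame of intervals.
#' @param what Label used in error messages.
#' @return `df` invisibly, as a tibble.
#' @export
validate_intervals <- function(df, what = "intervals") {
  df <- as_tibble(df)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s must have columns %s (missing: %s)", what,
                  paste(need, collapse = ", "),
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(as.character(df$chrom)) | is.na(df$chrom))) {
    abort(sprintf("%s: chrom names must be non-empty", what))
  }
  if (any(df$start != floor(df$start)) || any(df$end != floor(df$end))) {
    abort(sprintf("%s: coordinates must be integers", what))
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid interval at row %d (need 0 <= start < end)",
                  what, bad[1]))
  }
  invisible(df)
}

#' Merge overlapping intervals
#'
#' Collapses a table of (possibly overlapping, unsorted) intervals into the
#' minimal sorted set of disjoint intervals covering the same bases.
#' Strand is ignored.
#'
#' @param df Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Tibble of disjoint intervals sorted by (chrom, start).
#' @export
merge_intervals <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- tbl_from_gr(GenomicRanges::reduce(gr_from_tbl(df)))
  arrange(out, .data$chrom, .data$start)
}

total_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(as.numeric(df$end) - as.numeric(df$start))
}
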