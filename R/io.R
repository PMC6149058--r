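# Readers for the plain-text formats the pipeline consumes: BED3+,
# UCSC RepeatMasker table dumps, HOMER peak text and chrom.sizes files.
# Everything is normalised to 0-based half-open coordinates on load.

read_data_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) &
    !startsWith(lines, "#") &
    !startsWith(lines, "track") &
    !startsWith(lines, "browser")
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t| +")

parse_coord <- function(x, path, lineno, what) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) | out != suppressWarnings(as.numeric(x)))
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: %s '%s' is not an integer",
                  path, lineno[bad[1]], what, x[bad[1]]))
  }
  out
}

#' Read a BED file of class intervals
#'
#' Reads BED3+ (tab- or space-separated, 0-based half-open). Lines starting
#' with `#`, `track` or `browser` are skipped. Intervals are returned sorted
#' by (chrom, start) and are *not* merged: overlap resolution belongs to
#' [build_partition()].
#'
#' @param path Path to a BED file.
#' @param class_label Optional sequence-class label attached as a `class`
#'   column (e.g. `"exon"`).
#' @return Tibble with `chrom`, `start`, `end` and, when `class_label` is
#'   given, `class`.
#' @export
read_bed <- function(path, class_label = NULL) {
  dat <- read_data_lines(path)
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  if (!is.null(class_label)) empty$class <- character()
  if (length(dat$lines) == 0) return(empty)
  fields <- split_fields(dat$lines)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: line %d has %d fields; BED needs at least 3",
                  path, dat$lineno[which(nf < 3)[1]], min(nf)))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = parse_coord(vapply(fields, `[[`, "", 2), path, dat$lineno, "start"),
    end = parse_coord(vapply(fields, `[[`, "", 3), path, dat$lineno, "end")
  )
  bad <- which(out$start < 0 | out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: need 0 <= start < end (got %d, %d)",
                  path, dat$lineno[bad[1]], out$start[bad[1]], out$end[bad[1]]))
  }
  if (!is.null(class_label)) out$class <- class_label
  arrange(out, .data$chrom, .data$start)
}

#' Read a chromosome sizes file
#'
#' Two-column `chrom<TAB>length` text as distributed with UCSC genomes.
#'
#' @param path Path to the file.
#' @return Tibble with `chrom` and `length` columns.
#' @export
read_chrom_sizes <- function(path) {
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) {
    return(tibble(chrom = character(), length = integer()))
  }
  fields <- split_fields(dat$lines)
  if (any(lengths(fields) < 2)) {
    abort(sprintf("%s: chrom sizes need two columns (chrom, length)", path))
  }
  tibble(
    chrom = vapply(fields, `[[`, "", 1),
    length = parse_coord(vapply(fields, `[[`, "", 2), path, dat$lineno,
                         "length")
  )
}

# RepeatMasker repClass labels -> the package's fixed category set.
# Trailing '?' (uncertain classifications) is stripped before lookup;
# anything unrecognised maps to "other".
rmsk_class_map <- c(
  LINE = "LINE", SINE = "SINE", LTR = "LTR",
  Low_complexity = "low_complexity", Simple_repeat = "simple_repeat",
  DNA = "DNA", Satellite = "satellite"
)

#' Repeat categories recognised by the package
#' @return Character vector of category labels.
#' @export
repeat_categories <- function() {
  c(unname(rmsk_class_map), "other")
}

normalize_repeat_category <- function(x) {
  x <- sub("\\?$", "", x)
  out <- unname(rmsk_class_map[x])
  ifelse(is.na(out), ifelse(x %in% repeat_categories(), x, "other"), out)
}

#' Construct a repeat catalog
#'
#' A repeat catalog is the genome-wide universe of repeat instances used by
#' the hypergeometric representation test: `N` total instances of which `K`
#' fall in each category.
#'
#' @param instances Tibble with `chrom`, `start`, `end`, `category`.
#' @return A `repeat_catalog` object: list with `instances` (tibble),
#'   `category_counts` (tibble of `category`, `K`) and `total` (`N`).
#' @export
repeat_catalog <- function(instances) {
  instances <- as_tibble(instances)
  validate_intervals(instances, "repeat instances")
  if (!"category" %in% names(instances)) {
    abort("repeat instances need a 'category' column")
  }
  instances$category <- normalize_repeat_category(as.character(instances$category))
  counts <- instances |>
    count(.data$category, name = "K") |>
    arrange(.data$category)
  structure(
    list(
      instances = arrange(instances, .data$chrom, .data$start),
      category_counts = counts,
      total = nrow(instances)
    ),
    class = "repeat_catalog"
  )
}

#' @export
print.repeat_catalog <- function(x, ...) {
  cat(sprintf("<repeat_catalog> %d instances in %d categories\n",
              x$total, nrow(x$category_counts)))
  print(x$category_counts)
  invisible(x)
}

#' Read a repeat catalog
#'
#' Accepts either a UCSC RepeatMasker `rmsk` table dump (tab-separated, with
#' `genoName`/`genoStart`/`genoEnd` in columns 6-8 and `repClass` in column
#' 12; `genoStart` is 0-based) or 4-column BED whose fourth column is the
#' repeat category. `repClass` values outside the known set map to
#' `"other"`.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default), `"rmsk"` or `"bed"`.
#' @return A [repeat_catalog()] object.
#' @export
read_repeatmasker <- function(path, dialect = c("auto", "rmsk", "bed")) {
  dialect <- match.arg(dialect)
  dat <- read_data_lines(path)
  if (length(dat$lines) == 0) {
    return(repeat_catalog(tibble(chrom = character(), start = integer(),
                                 end = integer(), category = character())))
  }
  fields <- split_fields(dat$lines)
  nf <- lengths(fields)
  if (dialect == "auto") {
    if (all(nf >= 12)) dialect <- "rmsk"
    else if (all(nf >= 4) && all(nf <= 6)) dialect <- "bed"
    else abort(sprintf(
      "%s: cannot identify dialect from %d columns; accepted dialects: 'rmsk' (UCSC table dump, >= 12 columns) or 'bed' (4-6 columns, category in column 4)",
      path, nf[1]))
  }
  if (dialect == "rmsk") {
    if (any(nf < 12)) {
      abort(sprintf("%s: rmsk dialect needs >= 12 columns (got %d)",
                    path, min(nf)))
    }
    instances <- tibble(
      chrom = vapply(fields, `[[`, "", 6),
      start = parse_coord(vapply(fields, `[[`, "", 7), path, dat$lineno,
                          "genoStart"),
      end = parse_coord(vapply(fields, `[[`, "", 8), path, dat$lineno,
                        "genoEnd"),
      category = vapply(fields, `[[`, "", 12)
    )
  } else {
    if (any(nf < 4)) {
      abort(sprintf("%s: bed dialect needs >= 4 columns (got %d)",
                    path, min(nf)))
    }
    instances <- tibble(
      chrom = vapply(fields, `[[`, "", 1),
      start = parse_coord(vapply(fields, `[[`, "", 2), path, dat$lineno,
                          "start"),
      end = parse_coord(vapply(fields, `[[`, "", 3), path, dat$lineno, "end"),
      category = vapply(fields, `[[`, "", 4)
    )
  }
  repeat_catalog(instances)
}

#' Read a peak set
#'
#' Reads peaks from BED3+ (0-based half-open) or HOMER peak text (comment
#' lines start `#`; columns PeakID, chr, start, end, strand with 1-based
#' inclusive coordinates, converted on load). Peaks lacking an id get
#' `peak_<i>` in file order.
#'
#' @param path Path to the peak file.
#' @param dialect `"bed"` (default) or `"homer"`.
#' @param label Optional condition label stored as the `label` attribute.
#' @return Tibble with `peak_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_peaks <- function(path, dialect = c("bed", "homer"), label = NULL) {
  dialect <- match.arg(dialect)
  dat <- read_data_lines(path)
  out <- tibble(peak_id = character(), chrom = character(),
                start = integer(), end = integer(), strand = character())
  if (length(dat$lines) > 0) {
    fields <- split_fields(dat$lines)
    nf <- lengths(fields)
    if (dialect == "bed") {
      if (any(nf < 3)) {
        abort(sprintf("%s: BED peaks need >= 3 columns", path))
      }
      out <- tibble(
        peak_id = ifelse(nf >= 4, vapply(fields, function(f)
          if (length(f) >= 4) f[[4]] else "", ""), NA_character_),
        chrom = vapply(fields, `[[`, "", 1),
        start = parse_coord(vapply(fields, `[[`, "", 2), path, dat$lineno,
                            "start"),
        end = parse_coord(vapply(fields, `[[`, "", 3), path, dat$lineno,
                          "end"),
        strand = vapply(fields, function(f)
          if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else ".", "")
      )
    } else {
      if (any(nf < 5)) {
        abort(sprintf("%s: HOMER peak text needs >= 5 columns", path))
      }
      start1 <- parse_coord(vapply(fields, `[[`, "", 3), path, dat$lineno,
                            "start")
      out <- tibble(
        peak_id = vapply(fields, `[[`, "", 1),
        chrom = vapply(fields, `[[`, "", 2),
        start = start1 - 1L,            # 1-based inclusive -> 0-based half-open
        end = parse_coord(vapply(fields, `[[`, "", 4), path, dat$lineno,
                          "end"),
        strand = vapply(fields, function(f)
          if (f[[5]] %in% c("+", "-")) f[[5]] else ".", "")
      )
    }
    missing_id <- is.na(out$peak_id) | !nzchar(out$peak_id)
    out$peak_id[missing_id] <- paste0("peak_", which(missing_id))
    dup <- duplicated(out$peak_id)
    if (any(dup)) {
      abort(sprintf("%s: duplicate peak id '%s'", path, out$peak_id[dup][1]))
    }
    validate_intervals(out, "peaks")
  }
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' Write a tibble as a TSV report
#'
#' Writes tab-separated text with a header row, preceded by `#`-prefixed
#' metadata lines (at minimum the package version and the fold-enrichment
#' convention used throughout: f = observed/expected, f > 1 means
#' over-represented).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Optional named character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, meta = character()) {
  hdr <- c(
    sprintf("# peakrep %s", as.character(packageVersion("peakrep"))),
    "# fold enrichment convention: f = observed/expected; f > 1 = over-represented",
    if (length(meta) > 0) paste0("# ", names(meta), ": ", meta)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
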