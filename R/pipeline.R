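# End-to-end orchestration: annotate -> differential -> tally ->
# representation -> enrichment, from a single config, with every stage's
# table written as TSV plus a run manifest. Stages run only when their
# inputs are configured; any stage failure aborts naming the stage.

#' Run the representation analysis pipeline
#'
#' Executes the configured stages in order and writes one TSV per result
#' table plus a `manifest.json` recording the config, package version and
#' row counts. Re-running on identical inputs reproduces identical tables.
#'
#' The config is a list (or path to a YAML file with the same structure):
#' \describe{
#'   \item{chrom_sizes}{path to a chrom sizes file, or a tibble.}
#'   \item{class_bed}{named list of class label -> BED path (or a single
#'     tibble with a `class` column).}
#'   \item{repeats}{path to an rmsk/BED repeat file, or a
#'     `repeat_catalog`.}
#'   \item{peaks}{path to a peak file, or a tibble.}
#'   \item{peak_dialect}{`"bed"` (default) or `"homer"`.}
#'   \item{region_counts}{path to a TSV with chrom, start, end, count_a,
#'     count_b, or a tibble.}
#'   \item{depth_a, depth_b}{total mapped reads per condition (required
#'     with region_counts).}
#'   \item{class_counts}{path to a TSV with class, count_a, count_b, or a
#'     tibble.}
#'   \item{rule, min_fold, max_p, pseudocount, yates}{analysis parameters,
#'     defaulting to max_overlap, 2, 1e-4, 0.5, FALSE.}
#' }
#'
#' @param config List or YAML path, see Details.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the computed result objects.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(rule = "max_overlap", min_fold = 2, max_p = 1e-4,
                   pseudocount = 0.5, yates = FALSE, peak_dialect = "bed")
  config <- modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  # manifest records scalar settings and paths; in-memory tables are
  # represented by their row counts below, not serialized
  manifest <- list(package = "peakrep",
                   version = as.character(packageVersion("peakrep")),
                   config = config[vapply(config, function(x)
                     is.atomic(x) && length(x) == 1, TRUE)],
                   tables = list())

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  emit <- function(df, file, meta = character()) {
    write_report_tsv(df, file.path(out_dir, file), meta)
    manifest$tables[[file]] <<- nrow(df)
  }
  load_tbl <- function(x, reader) if (is.character(x)) reader(x) else as_tibble(x)

  partition <- NULL
  catalog <- NULL
  if (!is.null(config$chrom_sizes) && !is.null(config$class_bed)) {
    partition <- stage("partition", {
      chrom_sizes <- load_tbl(config$chrom_sizes, read_chrom_sizes)
      class_intervals <- if (is.data.frame(config$class_bed)) {
        as_tibble(config$class_bed)
      } else {
        bind_rows(purrr::imap(config$class_bed, function(p, cls)
          read_bed(p, class_label = cls)))
      }
      build_partition(class_intervals, chrom_sizes)
    })
    emit(class_occupancy_report(partition), "class_occupancy.tsv")
    results$partition <- partition
  }
  if (!is.null(config$repeats)) {
    catalog <- stage("repeats", {
      if (inherits(config$repeats, "repeat_catalog")) config$repeats
      else read_repeatmasker(config$repeats)
    })
    emit(catalog$category_counts, "repeat_catalog.tsv")
    results$catalog <- catalog
  }

  if (!is.null(config$peaks) && !is.null(partition)) {
    annotated <- stage("annotate", {
      peaks <- if (is.character(config$peaks)) {
        read_peaks(config$peaks, dialect = config$peak_dialect)
      } else as_tibble(config$peaks)
      annotate_peaks(peaks, partition, catalog, rule = config$rule)
    })
    emit(annotated, "annotated_peaks.tsv",
         c(note = "class tallies count peaks, not bp"))
    results$annotated <- annotated

    tally <- stage("tally", tally_classes(
      annotated, classes = unique(partition$intervals$class)))
    emit(tally$by_class, "class_tally.tsv")
    if (nrow(tally$by_repeat) > 0) emit(tally$by_repeat, "repeat_tally.tsv")
    results$tally <- tally

    if (tally$total > 0) {
      rep_cls <- stage("represent",
                       class_representation(tally, partition,
                                            correct = config$yates))
      emit(rep_cls, "class_representation.tsv")
      results$class_representation <- rep_cls
    }
    if (!is.null(catalog) && tally$n_with_repeat > 0) {
      rep_rep <- stage("represent", repeat_representation(tally, catalog))
      emit(rep_rep, "repeat_representation.tsv")
      results$repeat_representation <- rep_rep
    }
  }

  if (!is.null(config$region_counts)) {
    calls <- stage("differential", {
      rc <- load_tbl(config$region_counts, function(p)
        as_tibble(utils::read.delim(p, comment.char = "#")))
      if (is.null(config$depth_a) || is.null(config$depth_b)) {
        abort("region_counts requires depth_a and depth_b")
      }
      call_differential(rc, config$depth_a, config$depth_b,
                        min_fold = config$min_fold, max_p = config$max_p,
                        pseudocount = config$pseudocount)
    })
    emit(calls, "differential_calls.tsv",
         c(min_fold = config$min_fold, max_p = config$max_p))
    results$differential <- calls
    if (!is.null(partition) && nrow(calls) > 0) {
      summ <- stage("differential",
                    differential_class_summary(calls, partition, catalog,
                                               rule = config$rule))
      emit(summ$A_over_B$by_class, "differential_increased_tally.tsv")
      emit(summ$B_over_A$by_class, "differential_decreased_tally.tsv")
      results$differential_summary <- summ
    }
  }

  if (!is.null(config$class_counts)) {
    enr <- stage("enrich", {
      cc <- load_tbl(config$class_counts, function(p)
        as_tibble(utils::read.delim(p, comment.char = "#")))
      transcript_class_enrichment(cc)
    })
    emit(enr, "transcript_enrichment.tsv")
    results$transcript_enrichment <- enr
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(results)
}
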