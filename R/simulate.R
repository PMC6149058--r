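# Seeded generators for toy genomes, repeat catalogs, peak sets, region
# counts and class-count tables with recorded ground truth. Each generator
# draws from its own named sub-seed stream, so adding one generator to a
# workflow never perturbs the output of another run from the same master
# seed.

sub_seed <- function(seed, name) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + sum(utf8ToInt(name))) %% .Machine$integer.max
}

with_sub_seed <- function(seed, name, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(sub_seed(seed, name), code)
}

# split `total` bp into `n` near-equal integer pieces
split_bp <- function(total, n) {
  base <- total %/% n
  rem <- total %% n
  rep(base, n) + c(rep(1L, rem), rep(0L, n - rem))
}

#' Simulate a toy annotated genome
#'
#' Generates a partitioned genome with configurable class bp fractions and
#' a repeat catalog with exact per-category instance counts. Class bp is
#' realised exactly (up to integer rounding, well within 2% absolute of the
#' targets); segment placement within each chromosome is random, the
#' intergenic residual fills the gaps. Defaults emulate a mouse-like
#' composition scaled to desk size: intergenic ~31% of the genome and LINE
#' elements 19% of all repeats.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param class_fractions Named numeric vector of target genome fractions
#'   per class (must sum to <= 1; the residual is intergenic).
#' @param repeat_counts Named integer vector of repeat instances per
#'   category (realised exactly).
#' @param segment_length Mean length of a contiguous class segment, bp.
#' @param repeat_length Length of each repeat instance, bp.
#' @param priority Class priority order for [build_partition()].
#' @return List with `partition` (a `genome_partition`), `catalog` (a
#'   `repeat_catalog`), `class_intervals` (the pre-partition input tibble),
#'   `chrom_sizes`, and `config` (the realised settings).
#' @export
sim_genome <- function(seed = NULL, n_chroms = 2, chrom_length = 500000,
                       class_fractions = c(
                         promoter = 0.035, TTS = 0.035, exon = 0.045,
                         `5UTR` = 0.005, `3UTR` = 0.02, CpG_island = 0.01,
                         small_RNA = 0.002, tRNA = 0.001, rRNA = 0.002,
                         intron = 0.535),
                       repeat_counts = c(
                         LINE = 950, SINE = 1500, LTR = 950,
                         low_complexity = 250, simple_repeat = 500,
                         DNA = 150, satellite = 50, other = 650),
                       segment_length = 2000, repeat_length = 200,
                       priority = class_priority()) {
  if (sum(class_fractions) > 1) {
    abort("class fractions exceed 1: no room for the genome")
  }
  if (any(class_fractions < 0) || any(repeat_counts < 0)) {
    abort("fractions and counts must be non-negative")
  }
  chrom_sizes <- tibble(chrom = paste0("chr", seq_len(n_chroms)),
                        length = as.integer(chrom_length))
  class_bp <- round(class_fractions * chrom_length)
  if (sum(class_bp) > chrom_length) {
    abort("requested class bp exceeds chromosome length: infeasible config")
  }
  with_sub_seed(seed, "genome", {
    per_chrom <- purrr::map(chrom_sizes$chrom, function(ch) {
      pieces <- purrr::imap(class_bp[class_bp > 0], function(bp, cls) {
        n <- max(1L, as.integer(round(bp / segment_length)))
        tibble(class = cls, len = split_bp(as.integer(bp), n))
      }) |> bind_rows()
      pieces <- pieces[sample(nrow(pieces)), ]
      n_gaps <- nrow(pieces) + 1L
      gap_bp <- chrom_length - sum(pieces$len)
      gaps <- as.integer(rmultinom(1, gap_bp, rep(1, n_gaps)))
      starts <- cumsum(gaps[seq_len(nrow(pieces))]) +
        cumsum(c(0L, pieces$len))[seq_len(nrow(pieces))]
      tibble(chrom = ch, start = as.integer(starts),
             end = as.integer(starts + pieces$len), class = pieces$class)
    })
    class_intervals <- bind_rows(per_chrom) |>
      arrange(.data$chrom, .data$start)

    n_rep <- sum(repeat_counts)
    rep_chrom <- sample(chrom_sizes$chrom, n_rep, replace = TRUE,
                        prob = chrom_sizes$length)
    rep_start <- floor(runif(n_rep, 0, chrom_length - repeat_length))
    instances <- tibble(
      chrom = rep_chrom,
      start = as.integer(rep_start),
      end = as.integer(rep_start) + as.integer(repeat_length),
      category = rep(names(repeat_counts), repeat_counts)
    )

    list(
      partition = build_partition(class_intervals, chrom_sizes, priority),
      catalog = repeat_catalog(instances),
      class_intervals = class_intervals,
      chrom_sizes = chrom_sizes,
      config = list(seed = seed, n_chroms = n_chroms,
                    chrom_length = chrom_length,
                    class_fractions = class_fractions,
                    repeat_counts = repeat_counts,
                    segment_length = segment_length,
                    repeat_length = repeat_length)
    )
  })
}

#' Simulate a peak set with planted class enrichment
#'
#' Places peaks on a partitioned genome with per-class sampling probability
#' proportional to `g_c * multiplier`, recording the intended class of
#' every peak as ground truth. Peaks land wholly inside a randomly chosen
#' segment of their class whenever the segment is long enough, so the
#' recorded truth agrees with the partition's own max-overlap assignment
#' for essentially all peaks (boundary effects allowed).
#'
#' @param partition A [build_partition()] result (e.g. from
#'   [sim_genome()]).
#' @param n_peaks Number of peaks.
#' @param class_enrichment Named multipliers on the genomic sampling
#'   probability (default 1 for every class). The measurable enrichment of
#'   a boosted class is `multiplier / sum_c(g_c * m_c)`.
#' @param peak_width Peak width, bp.
#' @param seed Integer seed.
#' @return List with `peaks` (tibble `peak_id`, `chrom`, `start`, `end`)
#'   and `truth` (tibble `peak_id`, `true_class`).
#' @export
sim_peaks <- function(partition, n_peaks, class_enrichment = c(),
                      peak_width = 500, seed = NULL) {
  stopifnot(inherits(partition, "genome_partition"))
  if (n_peaks == 0) {
    return(list(
      peaks = tibble(peak_id = character(), chrom = character(),
                     start = integer(), end = integer()),
      truth = tibble(peak_id = character(), true_class = character())
    ))
  }
  occ <- filter(partition$occupancy, .data$fraction > 0)
  mult <- rep(1, nrow(occ))
  names(mult) <- occ$class
  known <- intersect(names(class_enrichment), occ$class)
  mult[known] <- class_enrichment[known]
  if (any(mult <= 0)) abort("enrichment multipliers must be > 0")
  probs <- occ$fraction * mult
  probs <- probs / sum(probs)

  chrom_len <- stats::setNames(partition$chrom_sizes$length,
                               partition$chrom_sizes$chrom)
  with_sub_seed(seed, "peaks", {
    cls_draw <- sample(occ$class, n_peaks, replace = TRUE, prob = probs)
    placed <- purrr::map(split(seq_len(n_peaks), cls_draw), function(idx) {
      cls <- cls_draw[idx[1]]
      ivl <- filter(partition$intervals, .data$class == cls)
      w <- ivl$end - ivl$start
      pick <- sample.int(nrow(ivl), length(idx), replace = TRUE, prob = w)
      maxoff <- w[pick] - peak_width
      off <- floor(runif(length(idx)) * pmax(maxoff + 1, 1))
      start <- ifelse(maxoff >= 0,
                      ivl$start[pick] + off,
                      ivl$start[pick] + (w[pick] %/% 2) - (peak_width %/% 2))
      start <- pmax(0, pmin(start, chrom_len[ivl$chrom[pick]] - peak_width))
      tibble(idx = idx, chrom = ivl$chrom[pick],
             start = as.integer(start),
             end = as.integer(start + peak_width), true_class = cls)
    }) |> bind_rows() |> arrange(.data$idx)
    peaks <- tibble(peak_id = paste0("peak_", placed$idx),
                    chrom = placed$chrom, start = placed$start,
                    end = placed$end)
    list(peaks = peaks,
         truth = tibble(peak_id = peaks$peak_id,
                        true_class = placed$true_class))
  })
}

#' Simulate per-region read counts at two depths
#'
#' Null/alternative model for the differential caller: background counts
#' `count_b ~ Poisson(base_rate)` and target counts `count_a ~
#' Poisson(base_rate * fold * depth_a/depth_b)`, with per-region true fold
#' changes recorded as ground truth.
#'
#' @param n_regions Number of regions.
#' @param base_rate Expected background reads per region (> 0). The
#'   default of 100 reflects the background coverage a ~1 kb candidate
#'   region carries at typical ChIP-seq depth; at much lower backgrounds
#'   the plug-in Poisson test alone grows anti-conservative and the fold
#'   gate carries the false-call control.
#' @param depth_a,depth_b Total mapped reads per condition.
#' @param fold True fold change(s), scalar or length `n_regions`
#'   (default 1 = null).
#' @param region_width Region width, bp (regions tile a synthetic
#'   chromosome).
#' @param seed Integer seed.
#' @return List with `counts` (tibble `region_id`, `chrom`, `start`,
#'   `end`, `count_a`, `count_b`) and `truth` (tibble `region_id`,
#'   `fold`).
#' @export
sim_region_counts <- function(n_regions = 1000, base_rate = 100,
                              depth_a = 1e7, depth_b = 1e7, fold = 1,
                              region_width = 1000, seed = NULL) {
  if (base_rate <= 0) abort("base_rate must be > 0")
  fold <- rep_len(fold, n_regions)
  if (any(fold <= 0)) abort("true folds must be > 0")
  r <- depth_a / depth_b
  with_sub_seed(seed, "regions", {
    counts <- tibble(
      region_id = paste0("region_", seq_len(n_regions)),
      chrom = "chrSim",
      start = as.integer((seq_len(n_regions) - 1) * region_width),
      end = as.integer(seq_len(n_regions) * region_width),
      count_a = rpois(n_regions, base_rate * fold * r),
      count_b = rpois(n_regions, base_rate)
    )
    list(counts = counts,
         truth = tibble(region_id = counts$region_id, fold = fold))
  })
}

#' Simulate a two-condition class-count table
#'
#' Multinomial transcript-class counts for two conditions, with optional
#' per-class proportion multipliers in condition A (renormalised), so the
#' expected measurable enrichment of each class is recorded as ground
#' truth.
#'
#' @param base_props Named baseline class proportions (normalised
#'   internally).
#' @param shift Named multipliers applied to condition A's proportions
#'   (default 1).
#' @param total_a,total_b Column totals (a minimum of 1 is enforced).
#' @param seed Integer seed.
#' @return List with `counts` (tibble `class`, `count_a`, `count_b`) and
#'   `truth` (tibble `class`, `expected_fold` = the proportion ratio the
#'   enrichment test should recover).
#' @export
sim_class_counts <- function(base_props = c(protein_coding = 0.70,
                                            LINE = 0.05, SINE = 0.04,
                                            low_complexity = 0.01,
                                            intergenic = 0.20),
                             shift = c(), total_a = 1e5, total_b = 1e5,
                             seed = NULL) {
  if (any(base_props <= 0)) abort("base proportions must be > 0")
  total_a <- max(1L, as.integer(round(total_a)))
  total_b <- max(1L, as.integer(round(total_b)))
  pb <- base_props / sum(base_props)
  mult <- rep(1, length(pb))
  names(mult) <- names(pb)
  known <- intersect(names(shift), names(pb))
  mult[known] <- shift[known]
  if (any(mult <= 0)) abort("shift multipliers must be > 0")
  pa <- pb * mult
  pa <- pa / sum(pa)
  with_sub_seed(seed, "class_counts", {
    counts <- tibble(
      class = names(pb),
      count_a = as.integer(rmultinom(1, total_a, pa)),
      count_b = as.integer(rmultinom(1, total_b, pb))
    )
    list(counts = counts,
         truth = tibble(class = names(pb), expected_fold = pa / pb))
  })
}
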