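# Loading class intervals and repeat catalogs, partition construction and
# occupancy baselines.

test_that("read_bed parses, sorts, skips comments and reports bad lines", {
  expect_equal(nrow(read_bed(bed_file(character()))), 0)

  p <- read_bed(bed_file(c("# a comment", "track name=x",
                           "chr1\t100\t200")))
  expect_equal(p, tibble::tibble(chrom = "chr1", start = 100L, end = 200L))

  # overlapping lines stay unmerged at load time; merging is the
  # partition's job
  two <- read_bed(bed_file(c("chr1\t100\t200", "chr1\t150\t300")))
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(100L, 150L))

  lbl <- read_bed(bed_file("chr1\t0\t10"), class_label = "exon")
  expect_equal(lbl$class, "exon")

  expect_error(read_bed(bed_file(c("chr1\t0\t10", "chr1\tfoo\t20"))),
               "line 2")
  expect_error(read_bed(bed_file("chr1\t300\t200")), "line 1")
  expect_error(read_bed(bed_file("chr1\t100")), "at least 3")
})

test_that("read_repeatmasker handles both dialects and category mapping", {
  rows <- c(
    rmsk_row("chr1", 0, 100, "LINE"),
    rmsk_row("chr1", 200, 300, "LINE"),
    rmsk_row("chr1", 400, 500, "SINE"),
    rmsk_row("chr2", 0, 100, "Low_complexity"),
    rmsk_row("chr2", 200, 300, "Simple_repeat"),
    rmsk_row("chr2", 400, 500, "Unknown"),
    rmsk_row("chr2", 600, 700, "DNA?"),
    rmsk_row("chr2", 800, 900, "LTR"),
    rmsk_row("chr3", 0, 100, "Satellite"),
    rmsk_row("chr3", 200, 300, "scRNA")
  )
  cat <- read_repeatmasker(write_tmp(rows))
  expect_s3_class(cat, "repeat_catalog")
  expect_equal(cat$total, 10)
  counts <- tibble::deframe(cat$category_counts)
  expect_equal(counts[["LINE"]], 2)
  expect_equal(counts[["SINE"]], 1)
  expect_equal(counts[["low_complexity"]], 1)
  expect_equal(counts[["simple_repeat"]], 1)
  expect_equal(counts[["DNA"]], 1)      # 'DNA?' normalised
  expect_equal(counts[["other"]], 2)    # Unknown + scRNA
  expect_equal(sum(cat$category_counts$K), cat$total)

  bed4 <- read_repeatmasker(write_tmp(c("chr1\t0\t50\tLINE",
                                        "chr1\t60\t90\tLINE",
                                        "chr1\t100\t140\tSINE")),
                            dialect = "bed")
  expect_equal(bed4$total, 3)
  expect_equal(tibble::deframe(bed4$category_counts)[["LINE"]], 2)

  expect_error(read_repeatmasker(write_tmp("chr1\t0\t50\tLINE\tx\ty\tz")),
               "dialect")
})

test_that("repeat counts are invariant under input row order", {
  rows <- c(rmsk_row("chr1", 0, 100, "LINE"),
            rmsk_row("chr1", 200, 300, "SINE"),
            rmsk_row("chr1", 400, 500, "LTR"),
            rmsk_row("chr2", 0, 100, "LINE"))
  a <- read_repeatmasker(write_tmp(rows))
  b <- read_repeatmasker(write_tmp(rev(rows)))
  expect_equal(a$category_counts, b$category_counts)
  expect_equal(a$total, b$total)
})

test_that("build_partition resolves overlaps by priority and fills the residual", {
  # single class: complement arithmetic
  p1 <- build_partition(
    tibble::tibble(chrom = "chr1", start = 0L, end = 300L, class = "exon"),
    tibble::tibble(chrom = "chr1", length = 1000L))
  occ <- tibble::deframe(p1$occupancy[c("class", "occupancy_bp")])
  expect_equal(occ[["exon"]], 300)
  expect_equal(occ[["intergenic"]], 700)
  expect_equal(p1$occupancy$fraction[p1$occupancy$class == "exon"], 0.3)

  # overlapping classes: exon beats intron on [100,200)
  p2 <- toy_partition()
  occ2 <- tibble::deframe(p2$occupancy[c("class", "occupancy_bp")])
  expect_equal(occ2[["exon"]], 200)
  expect_equal(occ2[["intron"]], 200)
  expect_equal(occ2[["intergenic"]], 600)

  # against the per-base oracle over the whole toy chromosome
  oracle <- perbase_oracle(
    tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(200L, 400L),
                   class = c("exon", "intron")),
    class_priority(), 1000)
  got <- lookup_class(p2, rep("chr1", 1000), 0:999)
  expect_equal(got, oracle)
})

test_that("build_partition validates its inputs", {
  cs <- tibble::tibble(chrom = "chr1", length = 1000L)
  expect_error(build_partition(
    tibble::tibble(chrom = "chr1", start = 0L, end = 1500L, class = "exon"),
    cs), "exceeds chromosome length")
  expect_error(build_partition(
    tibble::tibble(chrom = "chr9", start = 0L, end = 10L, class = "exon"),
    cs), "absent from chrom_sizes")
  expect_error(build_partition(
    tibble::tibble(chrom = "chr1", start = 0L, end = 10L, class = "intergenic"),
    cs), "residual")
  expect_error(build_partition(
    tibble::tibble(chrom = "chr1", start = 0L, end = 10L, class = "blob"),
    cs), "not in priority")
})

test_that("partition invariants hold on random class sets", {
  withr::with_seed(42, {
    for (rep_i in 1:3) {
      L <- 5000L
      ci <- tibble::tibble(
        chrom = "chr1",
        start = as.integer(sample(0:(L - 200), 30)),
        class = sample(c("promoter", "exon", "intron", "CpG_island"),
                       30, replace = TRUE)
      )
      ci$end <- ci$start + as.integer(sample(50:400, 30, replace = TRUE))
      ci$end <- pmin(ci$end, L)
      part <- build_partition(ci, tibble::tibble(chrom = "chr1", length = L))

      # completeness + exclusivity at sampled positions vs per-base oracle
      oracle <- perbase_oracle(ci, class_priority(), L)
      pos <- sample(0:(L - 1), 500)
      expect_equal(lookup_class(part, rep("chr1", 500), pos),
                   oracle[pos + 1])

      # occupancy conservation, exactly
      expect_equal(sum(part$occupancy$occupancy_bp), L)
      expect_equal(sum(part$occupancy$fraction), 1, tolerance = 1e-12)

      # merge idempotence: rebuilding from the partition's own intervals
      # reproduces identical occupancy (classes fully shadowed by a
      # higher-priority class have no intervals left to round-trip)
      again <- build_partition(
        dplyr::filter(part$intervals, class != "intergenic"),
        tibble::tibble(chrom = "chr1", length = L))
      expect_equal(dplyr::filter(again$occupancy, occupancy_bp > 0),
                   dplyr::filter(part$occupancy, occupancy_bp > 0))

      # partition intervals are disjoint
      ints <- dplyr::arrange(part$intervals, chrom, start)
      expect_true(all(ints$start[-1] >= ints$end[-nrow(ints)]))
    }
  })
})

test_that("class_occupancy_report computes fractions and renders percents", {
  p <- build_partition(
    tibble::tibble(chrom = "chr1", start = 0L, end = 999L, class = "exon"),
    tibble::tibble(chrom = "chr1", length = 1000L))
  # near-total class
  rep1 <- class_occupancy_report(p)
  expect_equal(sum(rep1$fraction), 1, tolerance = 1e-9)

  rep2 <- class_occupancy_report(toy_partition())
  expect_equal(tibble::deframe(rep2[c("class", "fraction")]),
               c(exon = 0.2, intron = 0.2, intergenic = 0.6))
  expect_equal(rep2$percent_label[rep2$class == "intergenic"], "60.00%")

  # direct published-occupancy input
  rep3 <- class_occupancy_report(
    tibble::tibble(class = c("intergenic", "rest"),
                   occupancy_bp = c(400, 600)))
  expect_equal(rep3$total_bp, rep(1000, 2))
  expect_equal(rep3$fraction, c(0.4, 0.6))
})
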