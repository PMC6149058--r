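# Fixtures are built in code at test time; writers return a tempfile path.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

bed_file <- function(rows) write_tmp(rows, ".bed")

# UCSC rmsk table dump rows: 17 columns, coords in 7/8 (0-based),
# repClass in column 12.
rmsk_row <- function(chrom, start, end, rep_class,
                     rep_name = "REP", rep_family = rep_class) {
  paste(c("0", "1000", "10", "10", "10", chrom, start, end, "-1000", "+",
          rep_name, rep_class, rep_family, "1", "100", "0", "1"),
        collapse = "\t")
}

homer_row <- function(id, chrom, start1, end1, strand = "+") {
  paste(c(id, chrom, start1, end1, strand, "1.0"), collapse = "\t")
}

# toy 1000-bp genome: exon [0,200) beats intron [100,400), rest intergenic
toy_partition <- function() {
  build_partition(
    tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                   end = c(200L, 400L), class = c("exon", "intron")),
    tibble::tibble(chrom = "chr1", length = 1000L)
  )
}

# independent per-base oracle: assign every base of one chromosome its
# class by direct marking; earlier-priority classes applied last so they
# overwrite later ones. Returns a character vector indexed by 0-based
# position + 1.
perbase_oracle <- function(class_intervals, priority, chrom_len) {
  vec <- rep("intergenic", chrom_len)
  present <- intersect(priority, unique(class_intervals$class))
  for (cls in rev(present)) {
    rows <- class_intervals[class_intervals$class == cls, ]
    for (i in seq_len(nrow(rows))) {
      vec[(rows$start[i] + 1):rows$end[i]] <- cls
    }
  }
  vec
}

# direct pmf summation of the Poisson upper tail, independent of ppois;
# sums the tail itself so tiny probabilities keep full relative accuracy
poisson_tail_oracle <- function(k, lambda) {
  if (k == 0) return(1)
  i <- seq(k, k + max(400, ceiling(20 * lambda)))
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# uniform draw from lo:hi that does not fall into sample()'s scalar trap
draw_between <- function(lo, hi) lo + sample.int(hi - lo + 1, 1) - 1

# full enumeration of the hypergeometric tail via binomial coefficients
hyper_tail_oracle <- function(k, n, K, N, upper = TRUE) {
  xs <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  if (upper) sum(pmf[xs >= k]) else sum(pmf[xs <= k])
}

# Fisher two-sided p by enumerating all tables with the observed margins:
# sum of probabilities no larger than the observed table's (with the
# standard tiny relative tolerance for ties)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  pmf <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  pobs <- pmf[xs == a]
  sum(pmf[pmf <= pobs * (1 + 1e-7)])
}

# step-up BH from the definition, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
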