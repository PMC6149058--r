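---
title: "Peak representation analysis: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak representation analysis: models, defaults and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakrep)
library(dplyr)
```

This vignette is the package's own account of the statistics it
implements: what each model assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## The questions the package answers

A ChIP-seq experiment for a broad repressive mark such as H3K27me3
produces tens of thousands of peaks. Three questions recur:

1. **Where are the peaks?** Every peak is assigned one sequence class
   (promoter, exon, intron, intergenic, ...) and at most one repeat
   category (LINE, SINE, LTR, ...), so that composition tallies are
   mutually exclusive and sum to the number of peaks.
2. **Which regions changed between two conditions?** Regions whose
   depth-normalised read counts differ by at least a fold threshold with
   a small cumulative-Poisson tail probability are called, separately in
   each direction.
3. **Is any class or category over- or under-represented?** Observed
   counts are compared to a genome-wide expectation: the class's genomic
   footprint for non-repeat classes, the repeat universe's category
   proportions for repeats, or the other condition's composition for
   transcript class tables.

## Genome partition and occupancy baselines

Class interval sets overlap in any real annotation (a promoter overlaps
the first exon, a CpG island overlaps the promoter). The partition
resolves this with an explicit, configurable priority list,
`class_priority()` = promoter, TTS, exon, 5UTR, 3UTR, CpG_island,
small_RNA, tRNA, rRNA, intron: within each class intervals are merged,
then the earlier class in the list claims shared bases, and everything
unclaimed becomes the intergenic residual. Annotation tools that assign a
single label per position use a hierarchy of this shape; making it an
argument makes it testable. Published per-class occupancy baselines do
not usually state their hierarchy, so when comparing against one, treat
the priority list as part of the comparison.

The total annotated genome size *G* is the sum of the supplied
chromosome lengths — an input, not something recomputed from annotation
files — and every class's baseline is *g~c~* = bp~c~/*G*. Two useful
identities hold exactly and are enforced: class occupancies sum to *G*,
and every base belongs to exactly one class (verified in the test suite
against a per-base marking oracle).

Coordinates are 0-based half-open everywhere internally; BED is native,
RepeatMasker `genoStart` is already 0-based, HOMER peak text is 1-based
inclusive and converted on load. Strand is ignored throughout: peaks are
unstranded and occupancy is a property of positions, not transcripts.

```{r occupancy}
g <- sim_genome(seed = 1)
class_occupancy_report(g$partition) |>
  select(class, occupancy_bp, fraction, percent_label) |>
  head(4)
```

## Peak class and repeat assignment

The default assignment rule is `max_overlap`: the class with the most
overlapping bp wins, ties broken by the priority order. The `midpoint`
rule (class containing `floor((start+end)/2)`) is kept because
single-position annotation is what some established tools do; the two
rules agree whenever a peak lies wholly inside one class region, which
the suite checks as a property. Repeat assignment is always by greatest
bp overlap, ties by category name order, `NA` when no repeat is touched.
A peak gets exactly one class and at most one repeat category, so
tallies are conservative by construction — no peak is counted twice, and
no multi-class fuzz needs resolving downstream. Tallies count peaks, not
bp; where a published figure might have counted either, the report
header says which this is.

## The differential caller

Given per-region counts (*n~A~*, *n~B~*) and total depths
(*D~A~*, *D~B~*), direction A-over-B uses

* λ = max(*n~B~*, pseudocount) · *D~A~*/*D~B~*,
* p = P(X ≥ *n~A~*) for X ~ Poisson(λ), via the survival function,
* FC = (*n~A~*/*D~A~*) / (max(*n~B~*, pseudocount)/*D~B~*) = *n~A~*/λ,

and calls the region iff FC ≥ `min_fold` (default 2) and p < `max_p`
(default 10⁻⁴, raw — the convention of the original count-based callers;
no multiple-testing correction is applied at this stage). The reciprocal
comparison with *r*⁻¹ gives B-over-A; swapping the two conditions maps
one direction's calls exactly onto the other's, a property the suite
asserts. The fold threshold applies to *normalised* counts; with unequal
depths this is the only self-consistent reading.

**Pseudocount.** The background count enters as the Poisson mean, so a
zero background would make the test degenerate. A floor of 0.5 on the
background count (configurable) keeps such regions testable while
perturbing large counts by nothing.

**Calibration and its limits.** The test treats the scaled background
count as a *known* mean, ignoring its own sampling noise. The
consequence, measured on simulated null data, is that the raw p < 10⁻⁴
tail alone fires on ~0.5% of null regions at any background rate — it is
anti-conservative as a standalone test. The caller as a whole is far
stricter because the ≥ 2-fold gate binds: at the generator's default
background of 100 reads per region the joint false-call fraction on 10⁴
null regions is 0 per direction, and it remains below 5 × 10⁻⁴ for
backgrounds above a few tens of reads. At very low backgrounds (~20
reads) the joint rate rises to ~0.7%, so sparse candidate regions should
be pre-filtered or interpreted cautiously. Power is not the bottleneck:
100 regions at a true fold of 4 over a background of 20 are recovered
with sensitivity ≥ 0.95.

## Representation statistics

**Repeats (hypergeometric).** The repeat universe is counted by
*instances*, not bp: *N* repeats genome-wide, *K* per category, and a
sample of *n* peaks (those overlapping any repeat) of which *k* fall in
the category. `p_over` = P(X ≥ k) and `p_under` = P(X ≤ k) for
X ~ Hypergeometric(N, K, n). Both tails are reported rather than a
single two-sided p because over- and under-representation are
biologically distinct findings for repeat families.

**Sequence classes (chi-square).** Observed *O~c~* of *T* peaks against
expectations (*T·g~c~*, *T*(1 − *g~c~*)), 1 df, two-sided, no continuity
correction by default (counts are large in any real peak set; the Yates
flag exists for small ones).

**Transcript class tables (Fisher).** Each class against the rest,
condition against condition, exact two-sided p by summing hypergeometric
table probabilities no larger than the observed table's. The reported
fold is the relative proportion ratio (class share in condition A over
its share in condition B); a fold of 1 is the no-enrichment dotted line
in the standard plot.

**Conventions, fixed once.** Fold enrichment is always
f = observed/expected, so f > 1 means over-represented; every report
header restates this because published prose sometimes uses the inverse
convention and a reader comparing numbers needs to know which way is up.
(One published worked example of the class representation arithmetic,
380/1158 rendered as 41.17%, is internally inconsistent — the quotient
is 32.82% — so this package computes true quotients and leaves
reconciliation to the reader.) Benjamini-Hochberg adjustment runs within
one family per report: all repeat categories together, all sequence
classes together, all transcript classes together. p-values are floored
at 10⁻³⁰⁰ and render as `<1e-300`, the "P ~ 0" of publication tables.

## The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. What it emulates, and the defaults chosen once:

* **Genome** (`sim_genome`): 2 chromosomes × 500 kb, class fractions
  chosen to give an intergenic residual of ~31% — the mouse genome's
  published intergenic share — with intron carrying most of the
  remainder, as in single-label genome annotations. Class bp targets are
  realised exactly up to integer rounding (well within the 2% contract);
  segments of mean length 2 kb are shuffled and spaced by random
  intergenic gaps.
* **Repeats**: 5000 instances of 200 bp with category counts realised
  exactly; the default mix puts LINE at 19% of all repeats, the mouse
  figure, with SINE the largest family.
* **Peaks** (`sim_peaks`): class drawn with probability ∝
  *g~c~* · multiplier, then placed inside a randomly chosen segment of
  that class, so the intended class matches the partition's own
  max-overlap assignment for ≥ 99% of peaks. Note the multipliers
  renormalise: a planted multiplier *m* on a class of fraction *g* is
  measurable as *m*/Σ*g~c~m~c~*, and that value — not *m* — is what
  recovery checks compare against.
* **Region counts** (`sim_region_counts`): background ~ Poisson(rate),
  target ~ Poisson(rate · fold · *D~A~*/*D~B~*), default rate 100 (see
  the calibration discussion above).
* **Class counts** (`sim_class_counts`): multinomial draws per condition
  with proportion multipliers in condition A; default composition is a
  germ-cell-like transcript mix dominated by protein-coding reads.

Each generator draws from its own named sub-seed stream derived from the
master seed, so adding a generator call to a workflow never changes the
draws of the others, and identical configs give byte-identical output.

What the generator does **not** emulate: nucleotide sequence,
mappability, read-level noise, peak-width variation, correlated
placement of repeats and classes, overdispersion beyond Poisson, or
biological replicate structure. Passing the recovery and calibration
checks therefore demonstrates that the *statistics and bookkeeping* are
correct at desk scale — not that any particular biological dataset would
yield particular numbers. Genome-scale results from real data (peak
counts in the tens of thousands, specific fold enrichments and
p-values) depend on the raw sequencing data and are out of reach of, and
out of scope for, the synthetic benchmarks.

## Numerical and design choices

* Tails via `ppois`/`phyper`/`pchisq` survival functions, never
  1 − CDF subtractions; the suite pins them against direct pmf-summation
  and enumeration oracles to 10⁻¹² relative accuracy.
* Degenerate inputs fail loudly: λ ≤ 0, T = 0, zero weights, intervals
  beyond chromosome ends, unknown chromosomes, duplicate peak ids and
  infeasible simulation configs are all errors naming the offending
  record, because silent coercion in annotation pipelines is how wrong
  baselines happen. The one deliberate exception: an *empty* peak file
  is an empty result, not an error.
* Duplicated or overlapping peaks are counted as supplied; merging is
  the caller's decision, not the tally's.
* `run_pipeline()` runs annotate → differential → tally →
  representation → enrichment, writes one TSV per table with `#`
  metadata lines, and a manifest with row counts; re-runs on identical
  inputs are byte-identical. Problem sizes in the shipped tests and the
  acceptance script (10⁴ null regions, 2000 replicate type-I runs,
  2000-peak recovery) were chosen as the smallest sizes at which the
  binomial noise of the measured rates is comfortably inside the
  asserted bands.

## Known limitations

* The class priority list is a modelling choice; two reasonable
  hierarchies give different promoter/exon splits near transcription
  starts, and no published baseline states its hierarchy precisely.
* The differential caller inherits the plug-in Poisson's optimism at low
  counts (above); for stringent genome-wide claims a count-model test
  with replicate-aware dispersion is the right escalation.
* Repeat representation by instance counts weights a 6 kb LINE and a
  300 bp SINE equally; a bp-weighted variant would answer a different
  question and is not provided.
* The haemocytometer conversion factor in `daily_sperm_production()` is
  protocol-specific and deliberately has no default.
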