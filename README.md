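# peakrep

Where do histone-mark ChIP-seq peaks sit in the genome, and does any
sequence class or repeat category carry more (or fewer) of them than its
genomic footprint predicts? `peakrep` answers this for peak sets such as
H3K27me3 ChIP-seq from foetal germ cells, where the interesting biology —
redistribution of a repressive mark over LINE/SINE/LTR retrotransposons,
introns and intergenic DNA — lives in *classes* of sequence rather than in
individual genes.

The package provides, as composable tibble-in/tibble-out functions:

* **Genome occupancy baselines.** Class interval sets (promoter, exon,
  intron, CpG island, ...) are merged and resolved into a disjoint
  partition under a configurable priority order (earlier class wins;
  intergenic is the residual), giving each class its genome fraction
  *g<sub>c</sub>* = bp<sub>c</sub> / *G*.
* **Peak annotation.** Each peak receives exactly one sequence class
  (max-overlap with priority tie-breaks, or midpoint rule) and at most one
  repeat category from a RepeatMasker-style catalog, so tallies are
  mutually exclusive and sum to the number of peaks.
* **Differential regions.** For per-region read counts in two conditions
  with total depths *D<sub>A</sub>*, *D<sub>B</sub>*, direction A-over-B
  takes λ = max(*n<sub>B</sub>*, 0.5) · *D<sub>A</sub>*/*D<sub>B</sub>* and
  calls a region when the depth-normalised fold change is ≥ 2 and the
  cumulative Poisson tail P(X ≥ *n<sub>A</sub>* | λ) < 10⁻⁴ (both
  thresholds configurable; the reciprocal comparison gives the other
  direction).
* **Representation statistics.** Repeat categories are tested
  hypergeometrically — observed *k* of *n* peaks in a category against *K*
  of *N* repeats genome-wide — and sequence classes by a 1-df chi-square of
  observed counts against *T·g<sub>c</sub>*. Transcript class tables are
  tested per class with 2×2 Fisher exact tests. Everywhere fold enrichment
  is *f* = observed/expected (*f* > 1 = over-represented) and
  Benjamini-Hochberg adjustment runs within each report family.
* **A seeded synthetic-data generator** (toy genomes, repeat catalogs,
  peak sets, region counts, class-count tables, all with recorded ground
  truth) so every stage can be exercised and calibrated at desk scale.

`run_pipeline()` orchestrates the stages from a single config (R list or
YAML) and writes each result as TSV plus a JSON manifest. Results have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` ggplot2 views.

## Worked example

Simulate a 2 × 500 kb genome, plant a two-fold enrichment of peaks on
exons, and ask which classes and repeat categories are over-represented:

```r
library(peakrep)
library(dplyr)

g   <- sim_genome(seed = 1)
sp  <- sim_peaks(g$partition, 1000, class_enrichment = c(exon = 2), seed = 2)
ann <- annotate_peaks(sp$peaks, g$partition, g$catalog)
t   <- tally_classes(ann)
glance(t)
#> # A tibble: 1 × 2
#>   total n_with_repeat
#>   <int>         <int>
#> 1  1000           972

class_representation(t, g$partition) |>
  select(class, observed, expected_count, fold, p_value, q, direction) |>
  arrange(q) |>
  head(3)
#> # A tibble: 3 × 7
#>   class    observed expected_count  fold       p_value            q direction
#>   <chr>       <dbl>          <dbl> <dbl>         <dbl>        <dbl> <chr>
#> 1 exon           84             45 1.87  0.00000000269 0.0000000296 over
#> 2 intron        499            535 0.933 0.0225        0.124        ns
#> 3 promoter       27             35 0.771 0.169         0.393        ns
```

Of 1000 peaks, 84 landed on exons where the genomic footprint predicts 45,
a fold enrichment of 1.87 ≈ the planted 2 (the renormalisation of the
sampling distribution makes the measurable value 2/1.045 ≈ 1.91);
the chi-square q-value flags it, and every other class stays at its
baseline. The hypergeometric repeat report reads the same way
(`repeat_representation(t, g$catalog)`), with `k`, `expected_count`,
`fold`, `p_over`/`p_under` and BH `q` per category.

The differential caller and the phenotype helper are one-liners:

```r
cumulative_poisson_p(40, 10)   # P(Pois(10) >= 40)
#> [1] 7.341636e-13
daily_sperm_production(52.5, 10, fragment_weight = 18.2, testis_weight = 95.4)
#> [1] 341147.5            # spermatids/day at the 4.84-day step 14-16 residence
```

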