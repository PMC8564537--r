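# mitomapr

Tidy tools for characterizing circular plant mitochondrial genomes.

Plant mitogenomes are frequently assembled as one or more circular
chromosomes carrying protein-coding genes (PCGs), tRNA and rRNA genes on
both strands, often trans-spliced across distant segments. Reports on a new
assembly conventionally tabulate the same battery of statistics:
nucleotide composition and strand skews, gene geometry on the circle,
codon-usage bias, a microsatellite census, and a concatenated gene
supermatrix for phylogenetics. `mitomapr` implements that battery as
composable, pipe-friendly functions over tibbles, so the numbers in such a
report can be recomputed, validated against the declared table values, and
exercised against simulated genomes with known ground truth.

The package was developed around the published *Neolamarckia cadamba*
mitogenome (GenBank MT320890 and MT364442; two circles of 109,836 and
305,144 bp, 83 genes) and ships a hand-transcribed copy of its annotation
tables as a test fixture, but every function is generic over any annotated
circular genome.

## The statistics

* **Strand skews.** For base counts `A`, `T`, `G`, `C` of a sequence,
  `AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)`. Skews are
  computed from raw counts (the percentage form cancels), sign-flip exactly
  under reverse complement, and are reported at whole-genome and
  gene-class resolution, with class sequences assembled gene-centrically
  (reverse-complementing N-strand genes).
* **Gene geometry.** Gene length is the exon sum over segments. The
  intergenic spacer between consecutive genes (ordered by first-segment
  start) is `start(next) − end(prev) − 1`, negative for overlaps, with an
  origin-wrapping record closing the circle. For trans-spliced genes,
  `end(prev)` is the largest segment end starting at or before the next
  gene, so distant downstream exons do not masquerade as local overlaps;
  `shared_bp` reports the true sequence-level intersection separately.
* **RSCU.** The relative synonymous codon usage of codon *c* in family *F*
  is `count(c) / mean(count over F)`: 1 means no bias, >1 a preferred
  (optimal) codon. Families sum to their size; Met and Trp are single-codon
  families with RSCU ≡ 1; the three stop codons form one family by default.
* **Repeats.** MISA-style maximal perfect microsatellites (unit 1–6 bp,
  default thresholds 10/6/5/5/5/5 copies) and an exact-period minisatellite
  scanner, both circular-aware, with canonical (least-rotation) motifs and
  a repeat-fraction summary.
* **Supermatrix.** Per-species gene sequences concatenated in a fixed
  24-gene order with a partition map, written as FASTA, relaxed PHYLIP and
  a RAxML-style partition file for downstream alignment/tree software.

A deterministic simulator (`simulate_genome()`, `simulate_species_set()`)
plants genes (any strand, trans-spliced layouts, chosen start/stop codons,
codon profiles) and repeats into background with configurable AT content
and skews, and returns the ground truth every statistic is checked against.

## Worked example

```r
library(mitomapr)
library(dplyr)

# the transcribed annotation table of the small published circle
f1 <- read_feature_table(
  system.file("extdata", "ncadamba_genome1_features.tsv", package = "mitomapr"),
  genome_length = 109836, genome_name = "genome1")

summarize_annotation(f1)
#> # A tibble: 1 × 5
#>     PCG  tRNA  rRNA other total
#>   <int> <int> <int> <int> <int>
#> 1     7     5     0     2    14

overlap_pairs(f1)
#> # A tibble: 1 × 4
#>   upstream_gene downstream_gene overlap_bp shared_bp
#>   <chr>         <chr>                <int>     <int>
#> 1 rpl16         rps3                   110       110
```

The circle holds 14 genes (7 PCGs, 5 tRNAs, 2 cytochrome c maturation
genes) and exactly one overlapping gene pair: rps3 starts 110 bp inside
rpl16.

Skews from the published per-circle base counts:

```r
bc <- ncadamba_published()$base_counts
tibble(circle = bc$name,
       at_skew = round(at_skew(bc), 4), gc_skew = round(gc_skew(bc), 4),
       at_content = round(at_content(bc), 2))
#> # A tibble: 2 × 4
#>   circle  at_skew gc_skew at_content
#>   <chr>     <dbl>   <dbl>      <dbl>
#> 1 genome1 -0.0128 -0.0241       54.4
#> 2 genome2 -0.0029  0.0058       54.9
```

Both circles are T-rich (negative AT-skew); the small circle is also
C-rich while the large one is slightly G-rich.

Codon usage on a simulated circle with known truth:

```r
genes <- bind_rows(gene_spec("cox1", length = 300),
                   gene_spec("nadX", strand = "N", length = 450, n_segments = 2))
sim <- simulate_genome(20000, genes = genes,
                       repeats = repeat_spec("AT", 8), seed = 42)
cu <- codon_usage(sim$genome, sim$features)
glance(cu)
#> # A tibble: 1 × 6
#>   total_codons dropped_nt ambiguous_codons n_optimal n_non_optimal n_no_preference
#> 1          250          0                0        27            30               7

find_ssrs(sim$genome)[, c("motif", "unit_len", "copies", "start", "end")]
#> # A tibble: 1 × 5
#>   motif unit_len copies start   end
#> 1 AT           2      8  5817  5832
```

The 750 bp of planted coding sequence chop into 250 codons, and the
planted (AT)8 microsatellite is recovered at its exact coordinates.
`autoplot(cu)` draws the per-amino-acid RSCU bars; `run_characterization()`
writes the full per-circle report bundle as TSVs.

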