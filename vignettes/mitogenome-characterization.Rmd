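---
title: "Characterizing circular plant mitochondrial genomes with mitomapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular plant mitochondrial genomes with mitomapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomapr)
library(dplyr)
```

## Scope and model

`mitomapr` characterizes an annotated circular mitochondrial genome — or
several circles forming one assembly — through five statistics families:
nucleotide composition with strand skews, gene geometry, codon usage
(RSCU), perfect-repeat detection, and supermatrix concatenation. It does
not assemble, annotate, align or build trees: annotations are inputs
(GenBank flat file or a feature TSV), and the supermatrix writers emit
files *for* external alignment and maximum-likelihood software.

The package was shaped around a two-circle plant mitogenome assembly
(109,836 + 305,144 bp, 83 genes including duplicated rRNA and ccm gene
copies), whose annotation tables ship in `inst/extdata/` as a
hand-transcribed fixture. Typographically ambiguous GC-content cells in
the source tables were left blank rather than guessed; the source's prose
and table disagree about one gene name (rpl18 vs rpl16) and the fixture
follows the table.

## Coordinates, strands, gene classes

Coordinates are 1-based inclusive throughout, matching GenBank and
published annotation tables; any half-open arithmetic stays internal. A
gene is an ordered list of segments; trans-spliced genes simply have
distant segments, and length is always the exon sum. Strands use the J/N
vocabulary common in organelle tables: J means the gene reads 5'→3' on
the stored sequence, N on its reverse complement. Categories are PCG,
tRNA, rRNA and other; maturase genes and ORFs count as PCGs, while
cytochrome c maturation (`ccm*`) and `mttB` genes fall under "other",
matching the accounting conventionally used in mitogenome reports.
Duplicated gene copies are counted individually.

## Composition and skews

`AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)`. Although the
definitions are usually stated in percentages, the percentages cancel, so
the package computes skews from raw counts and avoids intermediate
rounding; reported values round half-away-from-zero to 4 decimals (2 for
percentages), with raw values retained in machine output. Zero
denominators raise errors rather than returning a silent 0. Ambiguity
codes are tallied as "other" and enter neither skew numerators nor
denominators. Per-class rows are computed on the concatenation of every
member gene's strand-oriented sequence — a gene-centric convention,
chosen because class-level skews describe gene sets, not raw strand
slices; a class with no members is flagged undefined rather than zero.

Two invariants pin the implementation down: skews flip sign exactly under
reverse complement, and every composition statistic is invariant under
rotation of a circular sequence.

## Gene geometry and the spacer convention

Genes are ordered by the start of their first segment; the spacer between
consecutive genes is `start(next) − end(prev) − 1` (negative = overlap,
zero = abutting), and on a circle one extra record wraps from the last
gene to the first with the genome length added to the downstream start.

The only genuinely open design point was what "end of prev" means for a
trans-spliced gene whose later exons lie far downstream — past several
other genes. Taking the maximum end over all segments would make such
exons swallow their neighbours as spurious overlaps; taking always the
first segment's end breaks multi-exon genes whose exons are local. The
package uses the largest end among segments that *start* at or before the
downstream gene's first start. On the shipped fixture this single rule
reproduces every one of the 81 declared intergenic values across both
circles (verified by the validation pass in the test suite), including
the three negative ones, and yields exactly one overlapping pair on the
small circle and two on the large one, matching the source report's
prose. Because a negative spacer can exceed the actual shared sequence
(a short tRNA nested inside a longer gene gives spacer −817 but only 65
shared bp), records carry both `spacer_bp` and `shared_bp`.

Declared-vs-computed disagreements are warnings collected into a
validation table, never hard errors: published tables are not always
internally consistent about their own conventions.

Coding fraction uses additive accounting (summed exon-sum lengths,
overlaps counted once per gene), again matching how such reports add
their tables up.

## Codon usage

CDS assembly follows the strand convention above; extraction is exact, so
a planted trans-spliced N-strand gene round-trips byte-identically in the
simulator tests. Counting chops from position 1 of each CDS in steps of
three under the standard genetic code (used by angiosperm mitochondrial
genes); a trailing partial codon is dropped with a warning (declared
lengths in real tables are not all divisible by three), and
ambiguity-containing codons are excluded but counted.

RSCU is the family mean ratio: `count / mean(family counts)`. Families
with no observations are undefined (`NA`), not zero. Stop codons form one
three-codon family by default — organelle codon-usage tables commonly
list TAA among preferred codons, which requires stops in the table — and
`exclude_stops = TRUE` offers the common alternative. Classification is
strict: RSCU > 1 optimal, < 1 non-optimal, = 1 no preference (Met, Trp,
and any evenly used family). A published 32/32 optimal/non-optimal split
that includes the two single-codon amino acids contradicts the strict
criterion; the package follows the criterion and exposes the counts via
`glance()` so readers can reconcile either convention.

The start/stop audit reports the first and last triplet of each PCG, flags
non-ATG starts (ACG starts are valid in plant mitochondria, where C-to-U
RNA editing restores ATG on the transcript; no editing inference is
attempted), and cross-checks declared codons where present. CDS shorter
than 6 nt are flagged, not audited.

## Repeat detection

`find_ssrs()` implements MISA semantics: maximal perfect runs of units
1–6 bp, default thresholds 10/6/5/5/5/5 copies, reported once at maximal
extent trimmed to whole copies, with the canonical motif being the
lexicographically least rotation of the unit (the observed phase is kept
alongside). Only primitive units are reported, so a poly-A run never
reappears as (AA)n. Detection works by lag-k self-comparison: a maximal
run of `s[i] == s[i+k]` of length r is a perfect period-k region of span
r + k. Overlapping candidate calls are resolved longest-span-first.
Circular genomes are scanned with an origin-spanning window of max-unit ×
max-threshold bases; a run crossing the origin is reported once, flagged,
with its end coordinate reduced modulo the length. Mononucleotide runs
interrupted by a single mismatch split (no mismatch tolerance). Adjacent
runs within 100 bp are tagged as a compound group but remain separate
records. One behavioural consequence of maximality worth knowing: a
planted repeat whose flank happens to extend its period can have its
reported whole-copy window shifted by up to one unit relative to the
planted phase.

`find_tandem_repeats()` extends the same exact-period scan to units of
7–100 bp (at least two full copies, total span ≥ 24 bp by default). It is
deliberately a perfect-repeat scanner: alignment-based detection of
imperfect minisatellites, as done by dedicated tandem-repeat software, is
out of scope and this simplification is the stated semantics, not an
approximation of that software.

## Supermatrix preparation

`build_supermatrix()` concatenates one sequence per gene per species in a
fixed order — the shipped default is the 24 protein-coding genes
customarily used for plant mitogenome phylogenies — and records a
partition map that tiles the concatenation exactly. Gene matching is
case-insensitive with a small synonym table (cytB = cob) because GenBank
annotations vary. Missing genes either drop the species (with a warning)
or gap-fill with the gene's modal length. Writers produce FASTA, relaxed
sequential PHYLIP and a `DNA, gene = start-end` partition file.
Alignment, model selection, tree search and bootstrap are non-goals.

## The simulator and what passing tests mean

`simulate_genome()` is the package's ground-truth machine. Background
bases are drawn i.i.d. with probabilities solved in closed form from the
targets: with AT fraction *a* and skew *s*, `P(A) = a(1+s)/2`,
`P(T) = a(1−s)/2`, and likewise for G/C — so expectations hit the targets
exactly and a 50 kb draw recovers planted skews within about ±0.01.
Defaults emulate the assembly the package was shaped around (AT 54.45%,
AT-skew −0.0128, GC-skew −0.0241). Genes are placed collision-free (explicit
placement allowed, e.g. to plant a 110 bp overlap), their coding
sequences drawn from a codon profile between chosen start/stop codons,
written reverse-complemented for N-strand genes and split across segments
for trans-spliced layouts. Repeats are stamped last; a repeat stamped
inside a gene becomes part of that gene's recorded coding sequence, as
with real in-gene microsatellites. Identical seeds give byte-identical
output.

The simulator emulates composition, annotation geometry, codon profiles
and planted repeats. It does not emulate real mitogenomic features such
as RNA editing, recombining repeat-mediated isoforms, heteroplasmy,
imperfect repeats, or phylogenetic rate heterogeneity
(`simulate_species_set()` uses a single Jukes–Cantor-style per-site
substitution probability). Passing tests therefore demonstrate that the
statistics are computed correctly on genomes whose truth is known — not
that any biological conclusion about a real genome is correct.

Problem sizes in the test-suite simulations (circles of 2–30 kb, species
sets of ≤5 × 24 genes) were chosen as the smallest scales at which the
stochastic bands above are meaningful; all discrete checks (lengths,
spacers, planted repeat spans, CDS round-trips) are exact at any scale.

## Numerical and degenerate-input choices

* Rounding for display is half-away-from-zero (4 d.p. skews, 2 d.p.
  percentages); raw values are never rounded internally.
* Undefined statistics (empty sequence, zero-count skew denominators,
  unobserved RSCU families, empty gene classes) are errors or `NA`s,
  never silent zeros.
* RSCU equality with 1 uses a 1e-9 tolerance when classifying.
* Empty annotation tables, single-gene circles (whose wrap spacer is the
  rest of the circle) and zero-repeat genomes all return well-formed
  empty or flagged results.
* `run_characterization()` embeds no timestamps; identical inputs give
  byte-identical report bundles. Sequence-free mode (feature tables plus
  declared lengths only) produces the accounting, geometry and validation
  sections, which is exactly what a transcribed annotation table supports.

## Known limitations

The GenBank reader is a minimal single-LOCUS parser for the feature keys
this domain uses (CDS, tRNA, rRNA, misc_feature); it is not a general
GenBank implementation. The minisatellite scanner finds perfect repeats
only. Per-gene declared GC validation is limited to what the source table
printed. The repeat census of a real assembly depends on the exact
thresholds its authors used; the package defaults are the common MISA
settings, and the shipped census reconstruction uses published totals
with synthetic minisatellite spans (labelled as such) where per-repeat
breakdowns were not published.
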