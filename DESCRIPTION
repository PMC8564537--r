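Package: mitomapr
Title: Characterization of Circular Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for characterizing circular (multi-chromosome) plant
    mitochondrial genomes from an annotated sequence or a gene feature table:
    nucleotide composition with AT/GC strand skews at whole-genome and
    gene-class resolution, circular-coordinate gene geometry (exon-sum
    lengths, intergenic spacers, overlap pairs, coding fraction), strand-aware
    codon usage and relative synonymous codon usage (RSCU) with an
    optimal-codon classification and start/stop codon audit, MISA-style
    perfect microsatellite and exact-period minisatellite detection, and
    ordered concatenation of protein-coding genes into a supermatrix for
    downstream phylogenetics. Includes a deterministic simulator of
    mitogenome-like circles with planted genes and repeats for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
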