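suppressPackageStartupMessages(library(dplyr))

fixture_path <- function(which) {
  system.file("extdata",
              sprintf("ncadamba_genome%d_features.tsv", which),
              package = "mitomapr")
}

load_fixture <- function(which) {
  lens <- c(109836L, 305144L)
  read_feature_table(fixture_path(which), genome_length = lens[which],
                     genome_name = sprintf("genome%d", which))
}

published <- ncadamba_published()

# tiny deterministic circle with two hand-placed genes for exact checks
toy_circle <- function() {
  # 1..9 pad, geneJ at 10..21 (ATGAAACCCTAA), pad, geneN at 30..41
  # geneN CDS = ATGTTTGGGTAA planted as revcomp on forward strand
  fwd_n <- revcomp("ATGTTTGGGTAA")
  seq <- paste0("CGCGCGCGC", "ATGAAACCCTAA", "CGCGCGCG", fwd_n, "CGCGCGCGC")
  genome <- mt_genome(seq, name = "toy")
  features <- dplyr::bind_rows(
    tibble::tibble(gene = "geneJ", category = "PCG", strand = "J",
                   segments = list(tibble::tibble(start = 10L, end = 21L))),
    tibble::tibble(gene = "geneN", category = "PCG", strand = "N",
                   segments = list(tibble::tibble(start = 30L, end = 41L))))
  list(genome = genome, features = mitomapr:::new_features(
    features, genome_name = "toy", genome_length = genome$length))
}
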