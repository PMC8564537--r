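#' Extract coding sequences
#'
#' Assembles the CDS of each (by default protein-coding) feature from the
#' genome: `J`-strand genes are the concatenation of their segment slices in
#' listed order; `N`-strand genes the reverse complement of each segment,
#' concatenated in reverse listed order. The result length equals the
#' exon-sum gene length.
#'
#' @param genome [mt_genome].
#' @param features Feature tibble.
#' @param categories Which categories to extract (default `"PCG"`).
#' @return Tibble with `gene`, `category`, `strand`, `length`, `cds`.
#' @export
extract_cds <- function(genome, features, categories = "PCG") {
  keep <- features$category %in% categories
  f <- features[keep, ]
  tibble(
    gene = f$gene,
    category = f$category,
    strand = f$strand,
    length = gene_length(f),
    cds = purrr::map_chr(seq_len(nrow(f)), function(i) {
      feature_sequence(genome, f$segments[[i]], f$strand[i])
    })
  )
}

#' Codon counts over a CDS pool
#'
#' Chops each coding sequence into non-overlapping triplets from its first
#' position and tallies them under the standard genetic code (universal code;
#' angiosperm mitochondrial genes use it). A trailing partial codon is
#' dropped with a warning; codons containing ambiguity codes are excluded
#' from the 64-codon table but counted.
#'
#' @param cds Character vector of coding sequences (or the tibble from
#'   [extract_cds()], whose `cds` column is used).
#' @return A `codon_usage` object: tibble with one row per codon (`codon`,
#'   `aa`, `count`) and attributes `total_codons`, `dropped_nt`,
#'   `ambiguous_codons`.
#' @examples
#' codon_counts("ATGTAA")
#' @export
codon_counts <- function(cds) {
  if (is.data.frame(cds)) cds <- cds$cds
  cds <- toupper(cds)
  dropped <- sum(nchar(cds) %% 3)
  if (dropped > 0) {
    warn(sprintf("%d trailing nucleotide(s) not forming a full codon dropped",
                 dropped))
  }
  triplets <- unlist(purrr::map(cds, function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n < 3) return(character())
    substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  }))
  clean <- stringr::str_detect(triplets, "^[ACGT]{3}$")
  ambiguous <- sum(!clean)
  code <- Biostrings::GENETIC_CODE
  tab <- table(factor(triplets[clean], levels = names(code)))
  out <- tibble(
    codon = names(code),
    aa = unname(code),
    count = as.integer(tab)
  )
  structure(out,
            class = c("codon_usage", class(out)),
            total_codons = sum(out$count),
            dropped_nt = as.integer(dropped),
            ambiguous_codons = as.integer(ambiguous))
}

codon_attrs <- function(x) {
  attributes(x)[c("total_codons", "dropped_nt", "ambiguous_codons")]
}

restore_codon_class <- function(out, template) {
  structure(out,
            class = c("codon_usage", class(tibble())),
            total_codons = attr(template, "total_codons"),
            dropped_nt = attr(template, "dropped_nt"),
            ambiguous_codons = attr(template, "ambiguous_codons"))
}

#' Relative synonymous codon usage
#'
#' For codon `c` in synonymous family `F`, `RSCU(c) = count(c) / mean of
#' counts over F`: the ratio of the focal codon's frequency to the mean
#' frequency of its synonyms. Families sum to their size; single-codon
#' families (ATG/Met, TGG/Trp) have RSCU exactly 1 when observed; families
#' with no observations get `NA` (undefined, not zero). By default the three
#' stop codons form one family; `exclude_stops` drops them from the table
#' instead.
#'
#' @param table A `codon_usage` object from [codon_counts()].
#' @param exclude_stops Drop stop codons rather than treating them as one
#'   synonymous family.
#' @return The table with an `rscu` column added.
#' @export
rscu <- function(table, exclude_stops = FALSE) {
  stopifnot(inherits(table, "codon_usage"))
  out <- tibble::as_tibble(table)
  if (exclude_stops) out <- filter(out, .data$aa != "*")
  out <- out %>%
    group_by(.data$aa) %>%
    mutate(rscu = if (sum(.data$count) > 0)
      .data$count / mean(.data$count) else NA_real_) %>%
    ungroup()
  restore_codon_class(out, table)
}

#' Classify codons by usage bias
#'
#' `RSCU > 1` is optimal (preferred), `RSCU < 1` non-optimal, `RSCU = 1`
#' no preference (which covers the single-codon amino acids Met and Trp and
#' any family with exactly even usage).
#'
#' @param table A `codon_usage` object with `rscu` computed (computed on the
#'   fly otherwise).
#' @param tol Numeric tolerance for equality with 1.
#' @return The table with a `class` column (`optimal`, `non_optimal`,
#'   `no_preference`, or `NA` for unobserved families).
#' @export
classify_codons <- function(table, tol = 1e-9) {
  if (!"rscu" %in% names(table)) table <- rscu(table)
  out <- tibble::as_tibble(table) %>%
    mutate(class = dplyr::case_when(
      is.na(.data$rscu) ~ NA_character_,
      abs(.data$rscu - 1) <= tol ~ "no_preference",
      .data$rscu > 1 ~ "optimal",
      TRUE ~ "non_optimal"
    ))
  restore_codon_class(out, table)
}

#' Full codon-usage analysis of a genome
#'
#' Convenience pipeline: extract every PCG's CDS, count codons, compute RSCU
#' and classify.
#'
#' @param genome [mt_genome] (or list; CDS pools are combined).
#' @param features Matching feature tibble or list.
#' @param exclude_stops Passed to [rscu()].
#' @return A `codon_usage` tibble with `codon`, `aa`, `count`, `rscu`, `class`.
#' @export
codon_usage <- function(genome, features, exclude_stops = FALSE) {
  genomes <- as_genome_list(genome)
  if (is.data.frame(features)) features <- list(features)
  pool <- unlist(purrr::map2(genomes, features,
                             ~ extract_cds(.x, .y)$cds))
  classify_codons(rscu(codon_counts(pool), exclude_stops = exclude_stops))
}

#' Start / stop codon audit
#'
#' First and last triplet of every protein-coding gene's extracted CDS,
#' flagged for canonical ATG starts and cross-checked against any declared
#' initiation/termination codons carried by the annotation. ACG starts are
#' reported as non-canonical but are valid in plant mitochondria (C-to-U RNA
#' editing restores ATG on the transcript); no editing inference is made.
#'
#' @param genome [mt_genome].
#' @param features Feature tibble; only `PCG` rows are audited.
#' @return Tibble with `gene`, `init_codon`, `term_codon`,
#'   `is_canonical_start`, `declared_init`, `declared_term`,
#'   `matches_declared` (`NA` when nothing is declared), `audited` (`FALSE`
#'   for CDS shorter than 6 nt, which are flagged, not audited).
#' @export
start_stop_audit <- function(genome, features) {
  cds <- extract_cds(genome, features, categories = "PCG")
  keep <- features$category == "PCG"
  decl_init <- if ("init_codon" %in% names(features)) {
    features$init_codon[keep]
  } else rep(NA_character_, nrow(cds))
  decl_term <- if ("term_codon" %in% names(features)) {
    features$term_codon[keep]
  } else rep(NA_character_, nrow(cds))
  audited <- cds$length >= 6
  init <- ifelse(audited, substr(cds$cds, 1, 3), NA_character_)
  term <- ifelse(audited, substr(cds$cds, cds$length - 2, cds$length),
                 NA_character_)
  tibble(
    gene = cds$gene,
    init_codon = init,
    term_codon = term,
    is_canonical_start = init == "ATG",
    declared_init = decl_init,
    declared_term = decl_term,
    matches_declared = ifelse(
      is.na(decl_init) & is.na(decl_term), NA,
      (is.na(decl_init) | decl_init == init) &
        (is.na(decl_term) | decl_term == term)),
    audited = audited
  )
}
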