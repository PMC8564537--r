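#' Core protein-coding genes for mitogenome phylogenetics
#'
#' The 24 protein-coding genes customarily concatenated for plant
#' mitogenome phylogenies (ATP synthase, cytochrome oxidase, cytochrome b,
#' NADH dehydrogenase, ribosomal protein and cytochrome c maturation genes),
#' in the package's fixed default order.
#'
#' @return Character vector of 24 gene names.
#' @export
core_gene_order <- function() {
  c("atp1", "atp6", "atp9",
    "cox1", "cox2", "cox3",
    "cob",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad7", "nad9",
    "rps12", "rps13", "rps3", "rps4",
    "ccmB", "ccmC", "ccmFc", "ccmFn")
}

# case-insensitive matching with common annotation synonyms
GENE_SYNONYMS <- c(cytb = "cob", cytB = "cob", cobA = "cob")

normalize_gene <- function(gene) {
  g <- tolower(gene)
  syn <- setNames(tolower(GENE_SYNONYMS), tolower(names(GENE_SYNONYMS)))
  unname(ifelse(g %in% names(syn), syn[g], g))
}

#' Build a concatenated supermatrix
#'
#' Concatenates one sequence per gene per species in a fixed gene order and
#' records the partition map. Gene-name matching is case-insensitive with a
#' small synonym table (`cytB` = `cob`). Under `missing_policy =
#' "drop_species"` a species lacking any ordered gene is excluded with a
#' warning; under `"gap_fill"` the missing block is filled with `-` of the
#' gene's modal length across species.
#'
#' @param gene_seqs Tibble with columns `species`, `gene`, `sequence` (one
#'   row per species-gene).
#' @param gene_order Ordered character vector of gene names; defaults to
#'   [core_gene_order()].
#' @param missing_policy `"drop_species"` or `"gap_fill"`.
#' @return A `supermatrix` object: tibble with `species` and `sequence`
#'   columns, with attribute `partitions` (tibble `gene`, `start`, `end`,
#'   1-based inclusive within the concatenation).
#' @export
build_supermatrix <- function(gene_seqs, gene_order = core_gene_order(),
                              missing_policy = c("drop_species", "gap_fill")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(gene_order) > 0,
            all(c("species", "gene", "sequence") %in% names(gene_seqs)))
  gs <- gene_seqs %>%
    mutate(gene_key = normalize_gene(.data$gene)) %>%
    arrange(.data$species, .data$gene_key)
  order_key <- normalize_gene(gene_order)
  gs <- filter(gs, .data$gene_key %in% order_key)
  species <- sort(unique(gene_seqs$species))
  have <- tidyr::expand_grid(species = species, gene_key = order_key) %>%
    left_join(select(gs, "species", "gene_key", "sequence"),
              by = c("species", "gene_key"))
  if (missing_policy == "drop_species") {
    lacking <- have %>% group_by(.data$species) %>%
      summarise(miss = any(is.na(.data$sequence)), .groups = "drop") %>%
      filter(.data$miss) %>% pull("species")
    if (length(lacking) > 0) {
      warn(sprintf("dropping species lacking ordered genes: %s",
                   paste(lacking, collapse = ", ")))
      have <- filter(have, !.data$species %in% lacking)
    }
  } else {
    modal_len <- have %>%
      filter(!is.na(.data$sequence)) %>%
      group_by(.data$gene_key) %>%
      summarise(len = {
        tab <- table(nchar(.data$sequence))
        as.integer(names(tab)[which.max(tab)])
      }, .groups = "drop")
    have <- have %>%
      left_join(modal_len, by = "gene_key") %>%
      mutate(sequence = if_else(is.na(.data$sequence),
                                strrep("-", dplyr::coalesce(.data$len, 0L)),
                                .data$sequence)) %>%
      select(-"len")
  }
  if (nrow(have) == 0) {
    return(structure(tibble(species = character(), sequence = character()),
                     class = c("supermatrix", class(tibble())),
                     partitions = tibble(gene = character(), start = integer(),
                                         end = integer())))
  }
  # partition lengths must be consistent across species
  lens <- have %>%
    mutate(nc = nchar(.data$sequence)) %>%
    group_by(.data$gene_key) %>%
    summarise(len = unique(.data$nc)[1],
              ok = dplyr::n_distinct(.data$nc) == 1, .groups = "drop")
  if (!all(lens$ok)) {
    abort(sprintf("gene(s) with unequal lengths across species: %s (align first or use gap_fill with equal-length inputs)",
                  paste(lens$gene_key[!lens$ok], collapse = ", ")))
  }
  lens <- lens[match(order_key, lens$gene_key), ]
  ends <- cumsum(lens$len)
  partitions <- tibble(gene = gene_order,
                       start = as.integer(ends - lens$len + 1L),
                       end = as.integer(ends))
  out <- have %>%
    mutate(gene_key = factor(.data$gene_key, levels = order_key)) %>%
    arrange(.data$species, .data$gene_key) %>%
    group_by(.data$species) %>%
    summarise(sequence = paste(.data$sequence, collapse = ""),
              .groups = "drop")
  structure(out, class = c("supermatrix", class(tibble())),
            partitions = partitions)
}

#' Partition map of a supermatrix
#'
#' @param x A `supermatrix`.
#' @return Tibble `gene`, `start`, `end`.
#' @export
partition_map <- function(x) {
  stopifnot(inherits(x, "supermatrix"))
  attr(x, "partitions")
}

#' Split a supermatrix back into genes
#'
#' Inverse of [build_supermatrix()] under `drop_species`: slices every
#' species' concatenation by the partition map.
#'
#' @param x A `supermatrix`.
#' @return Tibble `species`, `gene`, `sequence`.
#' @export
split_supermatrix <- function(x) {
  parts <- partition_map(x)
  tidyr::expand_grid(species = x$species, gene = parts$gene) %>%
    left_join(parts, by = "gene") %>%
    left_join(tibble(species = x$species, full = x$sequence), by = "species") %>%
    mutate(sequence = substr(.data$full, .data$start, .data$end)) %>%
    select("species", "gene", "sequence")
}

#' Write a supermatrix to FASTA
#'
#' @param x A `supermatrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_supermatrix_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(setNames(x$sequence, x$species))
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Write a supermatrix in relaxed sequential PHYLIP
#'
#' @param x A `supermatrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_supermatrix_phylip <- function(x, path) {
  n <- nrow(x)
  len <- if (n > 0) nchar(x$sequence[1]) else 0
  lines <- c(sprintf(" %d %d", n, len),
             sprintf("%s  %s", x$species, x$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One line per gene: `DNA, gene = start-end`.
#'
#' @param x A `supermatrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition_file <- function(x, path) {
  p <- partition_map(x)
  writeLines(sprintf("DNA, %s = %d-%d", p$gene, p$start, p$end), path)
  invisible(path)
}
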