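#' Read a GenBank flat file
#'
#' Minimal single-LOCUS GenBank reader covering what organelle annotation
#' work needs: the sequence, and `CDS` / `tRNA` / `rRNA` / `misc_feature`
#' features with plain, `join(...)` and `complement(...)` locations. Joined
#' intervals become ordered segments; complemented locations map to strand
#' `N`; a join whose intervals step back past the origin is split as written
#' and flagged `wraps_origin`.
#'
#' @param path GenBank flat file.
#' @return List with `genome` ([mt_genome]) and `features` (feature tibble).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) abort("no LOCUS line")
  locus_name <- stringr::str_split_1(stringr::str_squish(locus[1]), " ")[2]
  circular <- grepl("circular", locus[1])
  o <- grep("^ORIGIN", lines)
  if (length(o) == 0) abort("missing sequence (no ORIGIN section)")
  seq_lines <- lines[(o[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) abort("missing sequence (empty ORIGIN)")
  genome <- mt_genome(sequence, name = locus_name, circular = circular)

  f0 <- grep("^FEATURES", lines)
  feats <- tibble(gene = character(), category = character(),
                  strand = character(), segments = list(),
                  init_codon = character(), term_codon = character(),
                  wraps_origin = logical())
  if (length(f0) > 0) {
    block <- lines[(f0[1] + 1):(o[1] - 1)]
    key_idx <- grep("^ {5}\\S", block)
    for (ki in seq_along(key_idx)) {
      i <- key_idx[ki]
      to <- if (ki < length(key_idx)) key_idx[ki + 1] - 1 else length(block)
      key <- stringr::str_split_1(stringr::str_squish(block[i]), " ")[1]
      if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "gene")) next
      body <- paste(stringr::str_trim(block[i:to]), collapse = " ")
      loc <- stringr::str_match(body, paste0("^", key, "\\s+([^/]+)"))[, 2]
      loc <- gsub("\\s", "", loc)
      strand <- if (grepl("^complement", loc)) "N" else "J"
      loc <- gsub("^complement\\(|^join\\(|\\)+$", "",
                  gsub("^complement\\(join\\(", "", loc))
      iv <- stringr::str_match_all(loc, "(\\d+)\\.\\.(\\d+)")[[1]]
      if (nrow(iv) == 0) next
      segs <- tibble(start = as.integer(iv[, 2]), end = as.integer(iv[, 3]))
      wraps <- nrow(segs) > 1 && any(diff(segs$start) < 0)
      gene <- stringr::str_match(body, '/gene="([^"]+)"')[, 2]
      note <- stringr::str_match(body, '/note="([^"]+)"')[, 2]
      init <- stringr::str_match(note, "init_codon:([ACGT]{3})")[, 2]
      term <- stringr::str_match(note, "term_codon:([ACGT]{3})")[, 2]
      category <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                    misc_feature = "other", gene = "other")[[key]]
      if (key == "misc_feature" || key == "gene") {
        category <- stringr::str_match(note, "category:(\\w+)")[, 2] %|na|% category
      }
      feats <- bind_rows(feats, tibble(
        gene = gene %|na|% sprintf("feature%d", ki), category = category,
        strand = strand, segments = list(segs),
        init_codon = init, term_codon = term, wraps_origin = wraps))
    }
  }
  list(genome = genome,
       features = new_features(feats, genome_name = genome$name,
                               genome_length = genome$length,
                               circular = genome$circular))
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Write a GenBank flat file
#'
#' Counterpart of [read_genbank()]: writes one LOCUS with the genome
#' sequence and one feature per annotation record (`CDS` for PCG, `tRNA`,
#' `rRNA`, `misc_feature` with a category note for `other`). Declared
#' initiation/termination codons are preserved in a `/note`.
#'
#' @param genome [mt_genome].
#' @param features Feature tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, features, path) {
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2000",
                   genome$name, genome$length,
                   if (genome$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s.", genome$name),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", genome$length))
  keymap <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", other = "misc_feature")
  for (i in seq_len(nrow(features))) {
    segs <- features$segments[[i]]
    loc <- paste(sprintf("%d..%d", segs$start, segs$end), collapse = ",")
    if (nrow(segs) > 1) loc <- sprintf("join(%s)", loc)
    if (features$strand[i] == "N") loc <- sprintf("complement(%s)", loc)
    key <- keymap[[features$category[i]]]
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf('                     /gene="%s"', features$gene[i]))
    notes <- c(
      if (features$category[i] == "other") "category:other",
      if (!is.na(features$init_codon[i]))
        sprintf("init_codon:%s", features$init_codon[i]),
      if (!is.na(features$term_codon[i]))
        sprintf("term_codon:%s", features$term_codon[i]))
    if (length(notes) > 0) {
      out <- c(out, sprintf('                     /note="%s"',
                            paste(notes, collapse = " ")))
    }
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1, genome$length, 60)
  for (p in pos) {
    chunk <- substr(genome$sequence, p, min(p + 59, genome$length))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
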