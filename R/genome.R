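#' Construct a circular genome object
#'
#' A lightweight container for one mitochondrial chromosome ("circle"): a
#' named nucleotide sequence with declared topology. Plant mitogenomes are
#' frequently assembled as more than one circular molecule; each circle is
#' represented by one `mt_genome`.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N` (case is
#'   normalized to upper). IUPAC ambiguity codes are accepted and treated as
#'   "other" by downstream counters.
#' @param name Label for the circle (e.g. `"genome1"`).
#' @param circular Logical; `TRUE` for a circular chromosome.
#' @return An object of class `mt_genome`: a list with elements `name`,
#'   `sequence`, `length` and `circular`.
#' @examples
#' g <- mt_genome("acgtACGT", name = "toy")
#' g$length
#' @export
mt_genome <- function(sequence, name = "genome", circular = TRUE) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "DNAStringSet")) {
    sequence <- as.character(sequence)[1]
  }
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq <- toupper(sequence)
  bad <- stringr::str_locate(seq, "[^ACGTNRYSWKMBDHV]")[1, "start"]
  if (!is.na(bad)) {
    abort(sprintf("non-IUPAC character '%s' at offset %d",
                  substr(seq, bad, bad), bad))
  }
  structure(
    list(name = name, sequence = seq, length = nchar(seq), circular = circular),
    class = "mt_genome"
  )
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %s: %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rotate a circular genome
#'
#' Moves the origin so that position `shift + 1` of the old sequence becomes
#' position 1. All composition statistics are invariant under rotation; the
#' helper exists mainly for validation of that property.
#'
#' @param genome An [mt_genome].
#' @param shift Number of bases to rotate by (0 to length - 1).
#' @return A rotated `mt_genome`.
#' @export
rotate_genome <- function(genome, shift) {
  stopifnot(inherits(genome, "mt_genome"), genome$circular)
  shift <- shift %% genome$length
  if (shift == 0) return(genome)
  s <- genome$sequence
  mt_genome(paste0(substr(s, shift + 1, genome$length), substr(s, 1, shift)),
            name = genome$name, circular = TRUE)
}

#' Extract the forward-strand slice of one segment
#'
#' @param genome An [mt_genome].
#' @param start,end 1-based inclusive coordinates; must lie within the genome.
#' @return Character scalar.
#' @keywords internal
segment_slice <- function(genome, start, end) {
  if (start < 1 || end > genome$length || end < start) {
    abort(sprintf("segment %d-%d outside genome '%s' (1-%d)",
                  start, end, genome$name, genome$length))
  }
  substr(genome$sequence, start, end)
}

#' Read a FASTA file into circular genome objects
#'
#' @param path FASTA file.
#' @param circular Logical, applied to every record.
#' @return A list of [mt_genome] objects, named by FASTA header (first word).
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- stringr::str_extract(names(ss), "^\\S+")
  purrr::map2(as.character(ss), nm, ~ mt_genome(.x, name = .y, circular = circular))
}

#' Write circular genomes to FASTA
#'
#' @param genomes An [mt_genome] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  genomes <- as_genome_list(genomes)
  ss <- Biostrings::DNAStringSet(purrr::map_chr(genomes, "sequence"))
  names(ss) <- purrr::map_chr(genomes, "name")
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

as_genome_list <- function(genomes) {
  if (inherits(genomes, "mt_genome")) genomes <- list(genomes)
  stopifnot(all(purrr::map_lgl(genomes, inherits, "mt_genome")))
  names(genomes) <- purrr::map_chr(genomes, "name")
  genomes
}
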