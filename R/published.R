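#' Published summary statistics for the Neolamarckia cadamba mitogenome
#'
#' Headline numbers reported for the published *N. cadamba* mitochondrial
#' genome assembly (GenBank MT320890, the 109,836 bp circle, and MT364442,
#' the 305,144 bp circle), shipped so the package's statistics can be
#' recomputed from them without downloading the accessions:
#'
#' * `base_counts` — per-circle A/C/G/T tallies (bp),
#' * `genome_lengths` — named lengths of the two circles,
#' * `pcg_total_bp` — reported total length of protein-coding sequence
#'   (37,521 bp),
#' * `coding_bp` — reported total coding length over all 83 genes
#'   (45,639 bp),
#' * `repeat_bp` — reported total repeat length (579 bp),
#' * `ssr_census` — reported microsatellite category counts (14 A/T
#'   mononucleotide, 2 G/C mononucleotide, 8 AT/TA dinucleotide, 2 GA
#'   dinucleotide runs) and 3 minisatellites.
#'
#' @return A named list; `base_counts` is a counts tibble compatible with
#'   [at_skew()] and friends.
#' @examples
#' at_skew(ncadamba_published()$base_counts)
#' @export
ncadamba_published <- function() {
  list(
    base_counts = tibble(
      name = c("genome1", "genome2"),
      a = c(29521L, 83584L), c = c(25616L, 68286L),
      g = c(24412L, 69089L), t = c(30287L, 84075L),
      other = c(0L, 0L), total = c(109836L, 305144L)
    ),
    genome_lengths = c(genome1 = 109836L, genome2 = 305144L),
    pcg_total_bp = 37521L,
    coding_bp = 45639L,
    repeat_bp = 579L,
    ssr_census = list(mono_at = 14L, mono_gc = 2L, di_atta = 8L, di_ga = 2L,
                      minisatellites = 3L)
  )
}

#' Reconstruct the published repeat census as records
#'
#' Builds a record table whose spans realize the published census: 14 A/T
#' and 2 G/C mononucleotide runs of 10 bp, 8 AT/TA and 2 GA dinucleotide
#' runs of 6 copies (12 bp), and 3 minisatellites whose spans fill the
#' published 579 bp total (the per-repeat breakdown is not published; the
#' minisatellite spans are the balancing term and are labelled synthetic).
#'
#' @return Record tibble compatible with [repeat_fraction()].
#' @export
published_repeat_census <- function() {
  mono <- tibble(
    unit = c(rep(c("A", "T"), each = 7), "G", "C"),
    unit_len = 1L, copies = 10L)
  di <- tibble(
    unit = c(rep(c("AT", "TA"), each = 4), "GA", "GA"),
    unit_len = 2L, copies = 6L)
  ssr_bp <- sum(mono$unit_len * mono$copies) + sum(di$unit_len * di$copies)
  remainder <- 579L - ssr_bp
  mini_units <- c(28L, 12L, 13L)
  mini_copies <- c(4L, 8L, 7L)
  stopifnot(sum(mini_units * mini_copies) == remainder)
  mini <- tibble(unit = strrep("N", mini_units), unit_len = mini_units,
                 copies = mini_copies)
  bind_rows(mono, di, mini) %>%
    mutate(motif = canonical_motif(.data$unit),
           span = .data$unit_len * .data$copies,
           start = NA_integer_, end = NA_integer_, wraps_origin = FALSE) %>%
    relocate("motif")
}
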