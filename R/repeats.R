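#' Canonical repeat motif
#'
#' The lexicographically least rotation of a repeat unit, so that phases of
#' the same tandem repeat (e.g. `AT` vs `TA`) share one canonical name. The
#' observed phase is retained separately on the record.
#'
#' @param unit Character vector of repeat units.
#' @return Character vector of canonical motifs.
#' @export
canonical_motif <- function(unit) {
  purrr::map_chr(unit, function(u) {
    k <- nchar(u)
    if (k == 1) return(u)
    rots <- purrr::map_chr(seq_len(k) - 1L,
                           ~ paste0(substr(u, .x + 1, k), substr(u, 1, .x)))
    min(rots)
  })
}

# TRUE if the unit cannot be written as a whole number of copies of a
# shorter unit (i.e. its minimal period equals its length)
is_primitive_unit <- function(u) {
  k <- nchar(u)
  if (k == 1) return(TRUE)
  divs <- which(k %% seq_len(k - 1) == 0)
  for (d in divs) {
    if (strrep(substr(u, 1, d), k / d) == u) return(FALSE)
  }
  TRUE
}

# maximal lag-k self-match runs on a linear string; returns tibble of
# candidate tandem spans (start, copies) with full copies only
lag_runs <- function(seq, k, min_copies) {
  n <- nchar(seq)
  if (n < k * 2) {
    return(tibble(start = integer(), unit = character(), copies = integer()))
  }
  ch <- strsplit(seq, "")[[1]]
  eq <- ch[seq_len(n - k)] == ch[(k + 1):n]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + k) >= min_copies * k
  if (!any(keep)) {
    return(tibble(start = integer(), unit = character(), copies = integer()))
  }
  tibble(
    start = starts[keep],
    copies = as.integer((r$lengths[keep] + k) %/% k),
    unit = substring(seq, starts[keep], starts[keep] + k - 1L)
  )
}

#' Find perfect microsatellites (SSRs)
#'
#' MISA-style detection of maximal perfect tandem repeats with unit lengths
#' 1-6 bp, each reported once at its maximal extent (trimmed to whole
#' copies). Only primitive units are reported (a poly-A run is `(A)n`, never
#' `(AA)m`). Circular genomes are scanned with an origin-spanning window of
#' `max unit x max threshold` bp so runs crossing the origin are found once,
#' flagged `wraps_origin`. Adjacent runs within `compound_gap` bp share a
#' `compound_group` tag but remain separate records.
#'
#' @param genome [mt_genome] (or plain sequence string).
#' @param thresholds Named vector: minimum copy number per unit length.
#'   Defaults to the MISA convention `c("1"=10,"2"=6,"3"=5,"4"=5,"5"=5,"6"=5)`.
#' @param features Optional feature tibble; each repeat overlapping a gene
#'   segment is annotated with that gene's name in `in_gene`.
#' @param compound_gap Max gap (bp) for compound grouping (MISA default 100).
#' @return Tibble of records: `motif` (canonical), `unit` (observed phase),
#'   `unit_len`, `copies`, `start`, `end`, `span`, `wraps_origin`,
#'   `compound_group`, `in_gene`.
#' @export
find_ssrs <- function(genome,
                      thresholds = c("1" = 10, "2" = 6, "3" = 5,
                                     "4" = 5, "5" = 5, "6" = 5),
                      features = NULL, compound_gap = 100) {
  if (!inherits(genome, "mt_genome")) genome <- mt_genome(genome)
  unit_lens <- as.integer(names(thresholds))
  recs <- scan_tandem(genome, unit_lens, min_copies = thresholds,
                      min_total = 1L,
                      window = max(unit_lens) * max(thresholds))
  recs <- annotate_in_gene(recs, features)
  recs <- recs[order(recs$start), ]
  if (nrow(recs) > 1) {
    gap_prev <- recs$start - dplyr::lag(recs$end) - 1L
    new_grp <- c(TRUE, gap_prev[-1] > compound_gap)
    grp <- cumsum(new_grp)
    sizes <- table(grp)
    recs$compound_group <- ifelse(sizes[as.character(grp)] > 1,
                                  as.integer(grp), NA_integer_)
  } else {
    recs$compound_group <- NA_integer_
  }
  recs
}

#' Find minisatellites (exact-period tandem repeats)
#'
#' A deliberately simple exact scanner for tandem repeats with units above
#' the SSR range: maximal runs where the sequence equals itself at lag `k`
#' (`min_unit <= k <= max_unit`), at least two full copies and a total span
#' of at least `min_total` bp. Only perfect repeats are found; no
#' alignment-based tolerance for imperfect copies is attempted. Overlapping
#' calls at different periods are resolved longest-span-first.
#'
#' @param genome [mt_genome] or sequence string.
#' @param min_unit,max_unit Unit length range (bp); `min_unit` must exceed 6.
#' @param min_total Minimum total span (bp).
#' @return Record tibble as in [find_ssrs()] (without compound grouping).
#' @export
find_tandem_repeats <- function(genome, min_unit = 7, max_unit = 100,
                                min_total = 24) {
  stopifnot(min_unit > 6)
  if (!inherits(genome, "mt_genome")) genome <- mt_genome(genome)
  unit_lens <- seq.int(min_unit, min(max_unit, genome$length %/% 2))
  if (length(unit_lens) == 0) return(empty_records())
  recs <- scan_tandem(genome, unit_lens,
                      min_copies = setNames(rep(2L, length(unit_lens)),
                                            unit_lens),
                      min_total = min_total,
                      window = 2L * min(max_unit, genome$length %/% 2))
  recs$compound_group <- NA_integer_
  recs$in_gene <- NA_character_
  recs[order(recs$start), ]
}

empty_records <- function() {
  tibble(motif = character(), unit = character(), unit_len = integer(),
         copies = integer(), start = integer(), end = integer(),
         span = integer(), wraps_origin = logical())
}

# shared scanning core: linear scan on (possibly origin-extended) sequence,
# primitive-unit filter, wrap deduplication, longest-first overlap resolution
scan_tandem <- function(genome, unit_lens, min_copies, min_total, window) {
  L <- genome$length
  ext <- if (genome$circular && L > 1) min(window, L - 1L) else 0L
  s <- paste0(genome$sequence, substr(genome$sequence, 1, ext))
  cands <- purrr::map(unit_lens, function(k) {
    runs <- lag_runs(s, k, min_copies[[as.character(k)]])
    if (nrow(runs) == 0) return(runs)
    runs$unit_len <- k
    runs
  })
  cands <- bind_rows(cands)
  if (nrow(cands) == 0) return(empty_records())
  cands <- cands %>%
    mutate(span = .data$unit_len * .data$copies,
           end = .data$start + .data$span - 1L) %>%
    filter(.data$span >= min_total,
           purrr::map_lgl(.data$unit, is_primitive_unit),
           .data$start <= L)
  if (nrow(cands) == 0) return(empty_records())
  # resolve overlaps (including the same run found at several primitive-
  # compatible periods): keep longest span first
  cands <- cands[order(-cands$span, cands$start, cands$unit_len), ]
  keep <- rep(TRUE, nrow(cands))
  taken_lo <- integer(0); taken_hi <- integer(0)
  for (i in seq_len(nrow(cands))) {
    lo <- cands$start[i]; hi <- cands$end[i]
    if (any(taken_lo <= hi & taken_hi >= lo)) {
      keep[i] <- FALSE
    } else {
      taken_lo <- c(taken_lo, lo); taken_hi <- c(taken_hi, hi)
    }
  }
  cands <- cands[keep, ]
  cands <- cands %>%
    mutate(
      wraps_origin = .data$end > L,
      end = ifelse(.data$end > L, .data$end - L, .data$end),
      motif = canonical_motif(.data$unit)
    ) %>%
    select("motif", "unit", "unit_len", "copies", "start", "end", "span",
           "wraps_origin") %>%
    arrange(.data$start)
  # a wrapping record makes its prefix at position 1 a duplicate detection
  wraps <- cands[cands$wraps_origin, ]
  if (nrow(wraps) > 0) {
    dup <- purrr::map_lgl(seq_len(nrow(cands)), function(i) {
      if (cands$wraps_origin[i]) return(FALSE)
      any(wraps$motif == cands$motif[i] & cands$end[i] <= wraps$end)
    })
    cands <- cands[!dup, ]
  }
  cands
}

annotate_in_gene <- function(recs, features) {
  recs$in_gene <- NA_character_
  if (is.null(features) || nrow(recs) == 0 || nrow(features) == 0) return(recs)
  for (i in seq_len(nrow(recs))) {
    for (j in seq_len(nrow(features))) {
      seg <- features$segments[[j]]
      if (any(seg$start <= recs$end[i] & seg$end >= recs$start[i])) {
        recs$in_gene[i] <- features$gene[j]
        break
      }
    }
  }
  recs
}

#' Repeat fraction of a genome
#'
#' Total repeat span as bp and as a percentage of total genome length.
#' Records are assumed non-overlapping (as returned by the finders).
#'
#' @param records Record tibble ([find_ssrs()] / [find_tandem_repeats()]
#'   output, possibly concatenated).
#' @param genome_length_total Total bp over all circles.
#' @return One-row tibble with `repeat_bp` and `percent`.
#' @export
repeat_fraction <- function(records, genome_length_total) {
  if (genome_length_total <= 0) abort("genome_length_total must be positive")
  tibble(repeat_bp = as.integer(sum(records$span)),
         percent = 100 * sum(records$span) / genome_length_total)
}
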