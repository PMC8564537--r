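#' Count bases in nucleotide sequences
#'
#' Exact tallies of `A`, `C`, `G`, `T`; every other (IUPAC ambiguity) letter
#' lands in `other`. Non-IUPAC characters are an error naming the offending
#' offset.
#'
#' @param sequence Character vector of nucleotide strings (or [mt_genome]
#'   objects / a list of them), case-insensitive.
#' @param name Optional labels for the output rows.
#' @return Tibble with one row per input: `name`, `a`, `c`, `g`, `t`,
#'   `other`, `total`.
#' @examples
#' count_bases("ACGT")
#' @export
count_bases <- function(sequence, name = NULL) {
  if (inherits(sequence, "mt_genome")) sequence <- list(sequence)
  if (is.list(sequence)) {
    name <- name %||% purrr::map_chr(sequence, "name")
    sequence <- purrr::map_chr(sequence, "sequence")
  }
  name <- name %||% paste0("seq", seq_along(sequence))
  seqs <- toupper(sequence)
  bad <- stringr::str_locate(seqs, "[^ACGTNRYSWKMBDHV]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("non-IUPAC character '%s' at offset %d",
                  substr(seqs[i], bad[i], bad[i]), bad[i]))
  }
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(
    ifelse(seqs == "", "A", seqs)))  # DNAStringSet drops empties' rows fine; guard
  freq[seqs == "", ] <- 0L
  tibble(
    name = name,
    a = as.integer(freq[, "A"]), c = as.integer(freq[, "C"]),
    g = as.integer(freq[, "G"]), t = as.integer(freq[, "T"]),
    other = as.integer(rowSums(freq) - freq[, "A"] - freq[, "C"] -
                         freq[, "G"] - freq[, "T"]),
    total = as.integer(rowSums(freq))
  )
}

#' Combine base-count rows
#'
#' @param counts Tibble from [count_bases()].
#' @param name Label for the combined row.
#' @return One-row counts tibble with summed tallies.
#' @export
combine_counts <- function(counts, name = "combined") {
  tibble(name = name,
         a = sum(counts$a), c = sum(counts$c), g = sum(counts$g),
         t = sum(counts$t), other = sum(counts$other), total = sum(counts$total))
}

as_counts <- function(counts) {
  if (is.character(counts) || inherits(counts, "mt_genome") ||
      (is.list(counts) && !is.data.frame(counts))) {
    counts <- count_bases(counts)
  }
  counts
}

#' AT skew
#'
#' `(A - T) / (A + T)`, computed from raw counts (algebraically identical to
#' the percentage form, without rounding). Negative values mean T-rich.
#' Ambiguity codes do not enter numerator or denominator.
#'
#' @param counts A counts tibble from [count_bases()] (any number of rows),
#'   or a sequence / [mt_genome] which is counted first.
#' @return Numeric vector in `[-1, 1]`.
#' @examples
#' at_skew(count_bases("AATT"))  # 0
#' @export
at_skew <- function(counts) {
  counts <- as_counts(counts)
  denom <- counts$a + counts$t
  if (any(denom == 0)) abort("AT skew undefined: A + T is zero")
  (counts$a - counts$t) / denom
}

#' GC skew
#'
#' `(G - C) / (G + C)`; see [at_skew()].
#'
#' @inheritParams at_skew
#' @return Numeric vector in `[-1, 1]`.
#' @export
gc_skew <- function(counts) {
  counts <- as_counts(counts)
  denom <- counts$g + counts$c
  if (any(denom == 0)) abort("GC skew undefined: G + C is zero")
  (counts$g - counts$c) / denom
}

#' AT and GC content
#'
#' `at_content` is `100 (A + T) / total`; `gc_content` is `100 (G + C) / total`.
#'
#' @inheritParams at_skew
#' @return Numeric vector of percentages.
#' @export
at_content <- function(counts) {
  counts <- as_counts(counts)
  if (any(counts$total == 0)) abort("AT content undefined on empty sequence")
  100 * (counts$a + counts$t) / counts$total
}

#' @rdname at_content
#' @export
gc_content <- function(counts) {
  counts <- as_counts(counts)
  if (any(counts$total == 0)) abort("GC content undefined on empty sequence")
  100 * (counts$g + counts$c) / counts$total
}

#' Strand-oriented sequence of one feature
#'
#' Concatenates the feature's segment slices: `J` features as stored, `N`
#' features as the reverse complement of each segment with segments taken in
#' reverse listed order (so the result always reads 5'->3' in the gene's own
#' sense).
#'
#' @param genome [mt_genome] carrying the feature.
#' @param segments Tibble of `start`/`end` pairs in listed order.
#' @param strand `"J"` or `"N"`.
#' @return Character scalar.
#' @export
feature_sequence <- function(genome, segments, strand) {
  slices <- purrr::map2_chr(segments$start, segments$end,
                            ~ segment_slice(genome, .x, .y))
  if (strand == "J") {
    paste(slices, collapse = "")
  } else {
    paste(rev(purrr::map_chr(slices, revcomp)), collapse = "")
  }
}

#' Composition and skew report per gene class
#'
#' For each circle, one row per requested class: `whole` is the full circle;
#' `PCG`, `tRNA`, `rRNA` and `other` rows are computed on the concatenation
#' of the strand-oriented sequence of every member gene (gene-centric
#' convention: skews are attributed to gene classes, not to raw strand
#' slices). When several circles are supplied a combined row per class sums
#' counts across circles.
#'
#' @param genomes [mt_genome] or list of them.
#' @param features Matching feature tibble or list (same order), or `NULL`
#'   for whole-genome rows only.
#' @param classes Character vector from `whole`, `PCG`, `tRNA`, `rRNA`, `other`.
#' @return Tibble with counts, `a_pct` ... `t_pct`, `at_content`,
#'   `gc_content`, `at_skew`, `gc_skew` per `(genome, class)`; skews are `NA`
#'   (flagged via `defined = FALSE`) for empty classes.
#' @export
composition_report <- function(genomes, features = NULL,
                               classes = c("whole", "PCG", "tRNA", "rRNA")) {
  genomes <- as_genome_list(genomes)
  if (is.data.frame(features)) features <- list(features)
  class_seq <- function(g, f, cl) {
    if (cl == "whole") return(g$sequence)
    if (is.null(f)) return(NA_character_)
    rows <- which(f$category == cl)
    if (length(rows) == 0) return("")
    paste(purrr::map_chr(rows, function(i) {
      feature_sequence(g, f$segments[[i]], f$strand[i])
    }), collapse = "")
  }
  per <- purrr::imap(genomes, function(g, nm) {
    f <- if (!is.null(features)) features[[match(nm, names(genomes))]] else NULL
    rows <- purrr::map(classes, function(cl) {
      s <- class_seq(g, f, cl)
      if (is.na(s)) return(NULL)
      cnt <- count_bases(s, name = nm)
      cnt$class <- cl
      cnt
    })
    bind_rows(rows)
  })
  out <- bind_rows(per)
  if (length(genomes) > 1) {
    comb <- out %>%
      group_by(.data$class) %>%
      summarise(across(c("a", "c", "g", "t", "other", "total"), sum),
                .groups = "drop") %>%
      mutate(name = "combined") %>%
      relocate("name")
    out <- bind_rows(out, comb)
  }
  out %>%
    mutate(
      defined = .data$total > 0,
      a_pct = ifelse(.data$defined, 100 * .data$a / .data$total, NA_real_),
      c_pct = ifelse(.data$defined, 100 * .data$c / .data$total, NA_real_),
      g_pct = ifelse(.data$defined, 100 * .data$g / .data$total, NA_real_),
      t_pct = ifelse(.data$defined, 100 * .data$t / .data$total, NA_real_),
      at_content = ifelse(.data$defined,
                          100 * (.data$a + .data$t) / .data$total, NA_real_),
      gc_content = ifelse(.data$defined,
                          100 * (.data$g + .data$c) / .data$total, NA_real_),
      at_skew = ifelse(.data$a + .data$t > 0,
                       (.data$a - .data$t) / (.data$a + .data$t), NA_real_),
      gc_skew = ifelse(.data$g + .data$c > 0,
                       (.data$g - .data$c) / (.data$g + .data$c), NA_real_)
    ) %>%
    relocate("name", "class")
}
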