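#' Gene annotation tables
#'
#' Annotations are ordinary tibbles with one row per gene copy and columns:
#'
#' * `gene` — gene name (duplicates allowed; plant mitogenomes carry repeated
#'   rRNA and ccm gene copies),
#' * `category` — one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"other"`,
#' * `strand` — `"J"` (the gene reads 5'->3' on the stored sequence) or `"N"`
#'   (it reads on the reverse complement),
#' * `segments` — list-column of tibbles with 1-based inclusive `start`/`end`
#'   pairs, in listed order; trans-spliced and multi-exon genes have several,
#' * `declared_length`, `declared_gc`, `init_codon`, `term_codon`,
#'   `declared_spacer` — optional values carried from the source table and
#'   used only for validation,
#' * `wraps_origin` — whether the feature's location crossed the origin in
#'   the source file (split into two segments on read).
#'
#' The table carries `genome_name`, `genome_length` and `circular` attributes
#' when known; functions that need them also take explicit arguments.
#'
#' @name mt_features
NULL

CATEGORIES <- c("PCG", "tRNA", "rRNA", "other")

new_features <- function(df, genome_name = NULL, genome_length = NULL,
                         circular = TRUE) {
  df <- tibble::as_tibble(df)
  need <- c("gene", "category", "strand", "segments")
  stopifnot(all(need %in% names(df)))
  for (col in c("declared_length", "declared_gc", "init_codon",
                "term_codon", "declared_spacer")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  if (!"wraps_origin" %in% names(df)) df$wraps_origin <- FALSE
  attr(df, "genome_name") <- genome_name
  attr(df, "genome_length") <- genome_length
  attr(df, "circular") <- circular
  df
}

features_meta <- function(features, genome_length = NULL, circular = NULL) {
  list(
    genome_length = genome_length %||% attr(features, "genome_length"),
    circular = circular %||% attr(features, "circular") %||% TRUE,
    genome_name = attr(features, "genome_name") %||% "genome"
  )
}

#' Parse a segment list string
#'
#' Accepts `"start-end"` ranges joined by `";"`. Hyphen and en-dash range
#' delimiters and thousands separators are tolerated; a leading `-` on the
#' start is not meaningful (coordinates are positive).
#'
#' @param x Character vector of segment strings.
#' @param line Optional line labels used in error messages.
#' @return List of tibbles with integer `start` and `end` columns.
#' @export
parse_segments <- function(x, line = seq_along(x)) {
  purrr::map2(x, line, function(s, ln) {
    s <- stringr::str_replace_all(s, ",", "")
    parts <- stringr::str_split_1(s, ";")
    parts <- stringr::str_trim(parts[parts != ""])
    if (length(parts) == 0) {
      abort(sprintf("line %s: empty segment list", ln))
    }
    m <- stringr::str_match(parts, "^(\\d+)\\s*[–-]\\s*(\\d+)$")
    if (anyNA(m[, 1])) {
      abort(sprintf("line %s: malformed position '%s'",
                    ln, parts[which(is.na(m[, 1]))[1]]))
    }
    seg <- tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
    if (any(seg$end < seg$start)) {
      abort(sprintf("line %s: segment end before start", ln))
    }
    seg
  })
}

format_segments <- function(segments) {
  purrr::map_chr(segments, ~ paste(sprintf("%d-%d", .x$start, .x$end),
                                   collapse = ";"))
}

#' Infer a gene category from its name
#'
#' tRNA and rRNA genes are recognized by name; cytochrome c maturation
#' (`ccm*`) and `mttB` genes fall in `"other"`, matching the usual accounting
#' in plant mitogenome reports; everything else (including ORFs and `matR`)
#' counts as a protein-coding gene.
#'
#' @param gene Character vector of gene names.
#' @return Character vector of categories.
#' @export
infer_category <- function(gene) {
  dplyr::case_when(
    stringr::str_detect(gene, stringr::regex("^(tRNA|trn)", ignore_case = TRUE)) ~ "tRNA",
    stringr::str_detect(gene, stringr::regex("^rrn", ignore_case = TRUE)) ~ "rRNA",
    stringr::str_detect(gene, stringr::regex("^(ccm|mttB)", ignore_case = TRUE)) ~ "other",
    TRUE ~ "PCG"
  )
}

#' Read a gene feature table
#'
#' Reads the tab-separated annotation dialect used by this package:
#' columns `gene`, `strand`, `segments` (semicolon-joined `start-end` ranges)
#' plus optional `category`, `length`, `gc`, `init_codon`, `term_codon` and
#' `intergenic` columns whose values are retained as declared metadata for
#' validation. Thousands separators and en-dash delimiters are tolerated in
#' positions.
#'
#' @param path TSV file.
#' @param genome_length Optional length (bp) of the circle the features sit on.
#' @param genome_name Optional label; defaults to the file name.
#' @param circular Logical topology flag.
#' @return A feature tibble (see [mt_features]).
#' @export
read_feature_table <- function(path, genome_length = NULL, genome_name = NULL,
                               circular = TRUE) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, strip.white = TRUE)
  raw <- tibble::as_tibble(raw)
  if (!all(c("gene", "strand", "segments") %in% names(raw))) {
    abort("feature table must have 'gene', 'strand' and 'segments' columns")
  }
  if (nrow(raw) == 0) {
    return(new_features(
      tibble(gene = character(), category = character(), strand = character(),
             segments = list()),
      genome_name = genome_name %||% basename(path),
      genome_length = genome_length, circular = circular))
  }
  bad_strand <- !raw$strand %in% c("J", "N")
  if (any(bad_strand)) {
    abort(sprintf("line %d: strand must be 'J' or 'N', got '%s'",
                  which(bad_strand)[1] + 1L, raw$strand[which(bad_strand)[1]]))
  }
  num <- function(col) {
    if (col %in% names(raw)) as.numeric(stringr::str_replace_all(raw[[col]], ",", ""))
    else rep(NA_real_, nrow(raw))
  }
  chr <- function(col) {
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  df <- tibble(
    gene = raw$gene,
    category = if ("category" %in% names(raw)) raw$category else infer_category(raw$gene),
    strand = raw$strand,
    segments = parse_segments(raw$segments, line = seq_len(nrow(raw)) + 1L),
    declared_length = as.integer(num("length")),
    declared_gc = num("gc"),
    init_codon = chr("init_codon"),
    term_codon = chr("term_codon"),
    declared_spacer = as.integer(num("intergenic"))
  )
  if (!all(df$category %in% CATEGORIES)) {
    abort(sprintf("unknown category '%s'",
                  setdiff(df$category, CATEGORIES)[1]))
  }
  if (!is.null(genome_length)) {
    ends <- purrr::map_int(df$segments, ~ max(.x$end))
    if (any(ends > genome_length)) {
      abort(sprintf("feature '%s' exceeds genome length %d",
                    df$gene[which(ends > genome_length)[1]], genome_length))
    }
  }
  new_features(df, genome_name = genome_name %||% basename(path),
               genome_length = genome_length, circular = circular)
}

#' Write a gene feature table
#'
#' Canonical writer for the TSV dialect read by [read_feature_table()]:
#' plain hyphens, no thousands separators.
#'
#' @param features Feature tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- tibble(
    gene = features$gene,
    category = features$category,
    strand = features$strand,
    segments = format_segments(features$segments),
    length = features$declared_length,
    gc = ifelse(is.na(features$declared_gc), NA,
                sprintf("%.2f", features$declared_gc)),
    init_codon = features$init_codon,
    term_codon = features$term_codon,
    intergenic = features$declared_spacer
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Count genes per category
#'
#' Tallies annotation records per category, counting duplicated gene copies
#' individually. Several annotation sets (one per circle) may be combined.
#'
#' @param features A feature tibble or a list of them.
#' @return One-row tibble with columns `PCG`, `tRNA`, `rRNA`, `other`, `total`.
#' @examples
#' f <- read_feature_table(
#'   system.file("extdata", "ncadamba_genome1_features.tsv", package = "mitomapr"))
#' summarize_annotation(f)
#' @export
summarize_annotation <- function(features) {
  if (is.data.frame(features)) features <- list(features)
  cats <- unlist(purrr::map(features, "category"))
  counts <- purrr::map_int(CATEGORIES, ~ sum(cats == .x))
  out <- tibble::as_tibble(as.list(setNames(counts, CATEGORIES)))
  out$total <- length(cats)
  out
}

#' Validate declared against computed feature values
#'
#' Checks, for every feature carrying declared metadata, that the exon-sum
#' length matches `declared_length` and that the recomputed intergenic spacer
#' matches `declared_spacer`. Mismatches are returned (and reported as
#' warnings), not raised as errors: published tables are not always internally
#' consistent about their own conventions.
#'
#' @param features Feature tibble.
#' @param genome_length,circular Geometry context (default: table attributes).
#' @return Tibble of mismatches with columns `gene`, `field`, `declared`,
#'   `computed`; zero rows when everything agrees.
#' @export
validate_annotation <- function(features, genome_length = NULL, circular = NULL) {
  meta <- features_meta(features, genome_length, circular)
  out <- tibble(gene = character(), field = character(),
                declared = numeric(), computed = numeric())
  if (nrow(features) == 0) return(out)
  len <- gene_length(features)
  bad_len <- !is.na(features$declared_length) & len != features$declared_length
  if (any(bad_len)) {
    out <- bind_rows(out, tibble(
      gene = features$gene[bad_len], field = "length",
      declared = as.numeric(features$declared_length[bad_len]),
      computed = as.numeric(len[bad_len])))
  }
  if (any(!is.na(features$declared_spacer)) && !is.null(meta$genome_length)) {
    sp <- intergenic_spacers(features, genome_length = meta$genome_length,
                             circular = meta$circular)
    key <- sp$downstream_idx
    comp <- setNames(sp$spacer_bp[!sp$wraps_origin], key[!sp$wraps_origin])
    idx <- which(!is.na(features$declared_spacer))
    for (i in idx) {
      ci <- comp[as.character(i)]
      if (!is.na(ci) && ci != features$declared_spacer[i]) {
        out <- bind_rows(out, tibble(
          gene = features$gene[i], field = "intergenic",
          declared = as.numeric(features$declared_spacer[i]),
          computed = as.numeric(ci)))
      }
    }
  }
  if (nrow(out) > 0) {
    warn(sprintf("%d declared value(s) disagree with computed values (%s)",
                 nrow(out), paste(unique(out$gene), collapse = ", ")))
  }
  out
}
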