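#' Run configuration for the characterization report
#'
#' Builds (and round-trips through YAML) the configuration consumed by
#' [run_characterization()]. Either sequences plus feature tables, or
#' feature tables alone (sequence-free mode: geometry and gene accounting
#' only).
#'
#' @param feature_tables Character vector of feature-table TSV paths.
#' @param genome_fastas Optional FASTA paths matching `feature_tables`
#'   (or a single multi-record FASTA path).
#' @param genome_lengths Optional named or positional lengths (bp), required
#'   in sequence-free mode for circular spacer arithmetic.
#' @param classes Gene classes for the composition section.
#' @param ssr_thresholds Named minimum copy numbers per SSR unit length.
#' @param circular Topology flag applied to every circle.
#' @param precision List of rounding digits used in the pretty report
#'   (`skew`, `percent`).
#' @param out_dir Output directory.
#' @param seed Seed recorded in the config (used only by simulation helpers).
#' @return A `run_config` list.
#' @export
run_config <- function(feature_tables, genome_fastas = NULL,
                       genome_lengths = NULL,
                       classes = c("whole", "PCG", "tRNA", "rRNA"),
                       ssr_thresholds = c("1" = 10, "2" = 6, "3" = 5,
                                          "4" = 5, "5" = 5, "6" = 5),
                       circular = TRUE,
                       precision = list(skew = 4, percent = 2),
                       out_dir = ".", seed = 1) {
  structure(list(feature_tables = feature_tables,
                 genome_fastas = genome_fastas,
                 genome_lengths = genome_lengths, classes = classes,
                 ssr_thresholds = ssr_thresholds, circular = circular,
                 precision = precision, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$ssr_thresholds <- as.list(x$ssr_thresholds)  # keep names through YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for the writer).
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (col in c("ssr_thresholds", "genome_lengths", "classes",
                "feature_tables", "genome_fastas")) {
    if (!is.null(x[[col]])) x[[col]] <- unlist(x[[col]])
  }
  do.call(run_config, x)
}

#' Run the full characterization and write a report bundle
#'
#' Orchestrates every stage on one or more circles and writes per-section
#' TSVs under `config$out_dir`: `gene_summary.tsv`, `geometry.tsv`,
#' `validation.tsv` (declared-vs-computed mismatches, empty when clean) and,
#' when sequences are available, `composition.tsv`, `rscu.tsv`,
#' `start_stop.tsv` and `ssr.tsv`. Outputs embed no timestamps; running
#' twice on identical inputs gives byte-identical files.
#'
#' @param config A [run_config()] (or a YAML path readable by
#'   [read_run_config()]).
#' @return Invisibly, a named list of the section tibbles.
#' @export
run_characterization <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config") ||
      length(config$feature_tables) == 0) {
    abort("usage: run_characterization(run_config(feature_tables = ...))")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- NULL
  if (!is.null(config$genome_fastas)) {
    genomes <- purrr::flatten(purrr::map(config$genome_fastas,
                                         read_genome_fasta,
                                         circular = config$circular))
    names(genomes) <- purrr::map_chr(genomes, "name")
  }
  lens <- config$genome_lengths
  features <- purrr::imap(config$feature_tables, function(p, i) {
    gl <- if (!is.null(genomes)) genomes[[i]]$length
          else if (!is.null(lens)) unname(lens[i]) else NULL
    read_feature_table(p, genome_length = gl,
                       genome_name = if (!is.null(genomes)) genomes[[i]]$name
                                     else basename(p),
                       circular = config$circular)
  })
  names(features) <- purrr::map_chr(features, ~ attr(.x, "genome_name"))

  sections <- list()
  per_genome <- purrr::imap(features,
                            ~ mutate(summarize_annotation(.x), genome = .y))
  sections$gene_summary <- bind_rows(c(
    unname(per_genome),
    list(mutate(summarize_annotation(features), genome = "combined")))) %>%
    relocate("genome")
  sections$geometry <- bind_rows(purrr::imap(
    features, ~ mutate(gene_geometry(.x), genome = .y))) %>% relocate("genome")
  sections$validation <- bind_rows(purrr::imap(
    features,
    ~ mutate(suppressWarnings(validate_annotation(.x)), genome = .y)))
  if (nrow(sections$validation) == 0) {
    sections$validation <- tibble(genome = character(), gene = character(),
                                  field = character(), declared = numeric(),
                                  computed = numeric())
  }
  total_len <- if (!is.null(genomes)) {
    sum(purrr::map_int(genomes, "length"))
  } else if (!is.null(lens)) sum(lens) else NA_integer_
  if (!is.na(total_len)) {
    sections$coding <- coding_fraction(features, total_len)
  }
  if (!is.null(genomes)) {
    sections$composition <- composition_report(genomes, features,
                                               classes = config$classes)
    sections$rscu <- tibble::as_tibble(codon_usage(genomes, features))
    sections$start_stop <- bind_rows(purrr::map2(
      genomes, features, ~ start_stop_audit(.x, .y)))
    sections$ssr <- bind_rows(purrr::imap(genomes, function(g, nm) {
      f <- features[[nm]]
      recs <- bind_rows(
        find_ssrs(g, thresholds = config$ssr_thresholds, features = f),
        find_tandem_repeats(g))
      if (nrow(recs) > 0) mutate(recs, genome = nm) else recs
    }))
    sections$repeat_fraction <- repeat_fraction(sections$ssr, total_len)
  } else {
    inform("no sequences supplied: composition, codon and repeat sections skipped")
  }
  for (nm in names(sections)) {
    out <- sections[[nm]]
    if ("segments" %in% names(out)) out$segments <- format_segments(out$segments)
    utils::write.table(out, file.path(config$out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(sections)
}
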