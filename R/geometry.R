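#' Exon-sum gene lengths
#'
#' Length of each gene as the sum of its segment lengths (`end - start + 1`),
#' the convention used for trans-spliced and multi-exon mitochondrial genes.
#'
#' @param features Feature tibble.
#' @return Integer vector, one value per feature, in input order.
#' @export
gene_length <- function(features) {
  purrr::map_int(features$segments,
                 ~ as.integer(sum(.x$end - .x$start + 1L)))
}

#' Gene length table
#'
#' @param features Feature tibble.
#' @return Tibble with `gene`, `category`, `strand`, `n_segments`, `length`.
#' @export
gene_lengths <- function(features) {
  tibble(
    gene = features$gene,
    category = features$category,
    strand = features$strand,
    n_segments = purrr::map_int(features$segments, nrow),
    length = gene_length(features)
  )
}

# Effective upstream end used for spacer arithmetic: the maximal segment end
# among the upstream gene's segments that START at or before the downstream
# gene's first start. Distant trans-spliced segments lying wholly beyond the
# downstream gene do not shorten the spacer; this is the single rule that
# reproduces every printed intergenic value in the reference tables.
effective_end <- function(segments, next_start) {
  s <- segments[segments$start <= next_start, , drop = FALSE]
  if (nrow(s) == 0) s <- segments[1, , drop = FALSE]
  max(s$end)
}

first_start <- function(features) {
  purrr::map_int(features$segments, ~ .x$start[1])
}

#' Intergenic spacers on a (circular) genome
#'
#' Orders genes by the start of their first segment and reports, for every
#' consecutive pair, the spacer `start(downstream) - end(upstream) - 1`.
#' Negative values are overlaps, zero means abutting genes. On a circular
#' genome one extra record wraps from the last gene back to the first, with
#' the genome length added to the downstream start.
#'
#' The upstream "end" is the largest segment end among upstream segments
#' starting at or before the downstream gene's first start, so that a
#' trans-spliced gene's distant downstream exons do not masquerade as local
#' overlaps. `shared_bp` additionally reports the true sequence-level overlap
#' (summed intersection of the two genes' segment sets), which can differ
#' from a negative spacer when one gene is nested inside another.
#'
#' @param features Feature tibble.
#' @param genome_length Circle length in bp (required when `circular`).
#' @param circular Logical; add the origin-wrapping record?
#' @return Tibble with columns `upstream_gene`, `downstream_gene`,
#'   `spacer_bp`, `shared_bp`, `wraps_origin`, plus `upstream_idx` /
#'   `downstream_idx` row indices into `features`.
#' @examples
#' f <- read_feature_table(
#'   system.file("extdata", "ncadamba_genome1_features.tsv", package = "mitomapr"),
#'   genome_length = 109836)
#' dplyr::filter(intergenic_spacers(f), spacer_bp < 0)
#' @export
intergenic_spacers <- function(features, genome_length = NULL, circular = NULL) {
  meta <- features_meta(features, genome_length, circular)
  if (nrow(features) == 0) {
    return(tibble(upstream_gene = character(), downstream_gene = character(),
                  spacer_bp = integer(), shared_bp = integer(),
                  wraps_origin = logical(), upstream_idx = integer(),
                  downstream_idx = integer()))
  }
  ord <- order(first_start(features))
  starts <- first_start(features)[ord]
  n <- length(ord)
  pairs <- if (meta$circular) cbind(seq_len(n), c(seq_len(n)[-1], 1L)) else
    cbind(seq_len(n - 1), seq_len(n)[-1])
  if (n == 1 && !meta$circular) {
    pairs <- matrix(integer(), ncol = 2)
  }
  rows <- purrr::map(seq_len(nrow(pairs)), function(k) {
    i <- ord[pairs[k, 1]]; j <- ord[pairs[k, 2]]
    wrap <- meta$circular && pairs[k, 2] == 1L && n > 0
    next_start <- first_start(features[j, ])
    if (wrap) {
      if (is.null(meta$genome_length)) {
        abort("genome_length required for the origin-wrapping spacer")
      }
      next_start <- next_start + meta$genome_length
    }
    up_end <- effective_end(features$segments[[i]], next_start)
    tibble(
      upstream_gene = features$gene[i], downstream_gene = features$gene[j],
      spacer_bp = as.integer(next_start - up_end - 1L),
      shared_bp = segments_shared(features$segments[[i]], features$segments[[j]]),
      wraps_origin = wrap, upstream_idx = i, downstream_idx = j
    )
  })
  out <- bind_rows(rows)
  if (n == 1 && meta$circular) return(out)  # single self-wrap record
  out
}

segments_shared <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    tot <- tot + sum(pmax(0L, hi - lo + 1L))
  }
  as.integer(tot)
}

#' Overlapping gene pairs
#'
#' Consecutive gene pairs whose intergenic spacer is negative.
#'
#' @inheritParams intergenic_spacers
#' @return Tibble with `upstream_gene`, `downstream_gene`, `overlap_bp`
#'   (`-spacer_bp`) and `shared_bp`.
#' @export
overlap_pairs <- function(features, genome_length = NULL, circular = NULL) {
  intergenic_spacers(features, genome_length, circular) %>%
    filter(.data$spacer_bp < 0) %>%
    mutate(overlap_bp = -.data$spacer_bp) %>%
    select("upstream_gene", "downstream_gene", "overlap_bp", "shared_bp")
}

#' Coding fraction of a genome
#'
#' Additive coding content: the sum of exon-sum gene lengths over every
#' feature (overlapping bases counted once per gene, matching the additive
#' accounting customary in mitogenome reports), as bp and as a percentage of
#' total genome length.
#'
#' @param features Feature tibble or list of them (one per circle), or a
#'   precomputed total coding length in bp.
#' @param genome_length_total Total bp across all circles.
#' @return One-row tibble with `coding_bp` and `percent`.
#' @export
coding_fraction <- function(features, genome_length_total) {
  if (is.data.frame(features)) features <- list(features)
  if (genome_length_total <= 0) abort("genome_length_total must be positive")
  coding <- if (is.numeric(features)) sum(features) else
    sum(purrr::map_int(features, ~ sum(gene_length(.x))))
  tibble(coding_bp = as.integer(coding),
         percent = 100 * coding / genome_length_total)
}

#' Full geometry table for one circle
#'
#' Per-gene lengths joined with the spacer to the next gene (sorted order).
#'
#' @inheritParams intergenic_spacers
#' @return Tibble with `gene`, `category`, `strand`, `n_segments`, `length`,
#'   `spacer_to_next`, `shared_with_next`, `wraps_origin`.
#' @export
gene_geometry <- function(features, genome_length = NULL, circular = NULL) {
  gl <- gene_lengths(features)
  sp <- intergenic_spacers(features, genome_length, circular)
  gl$spacer_to_next <- NA_integer_
  gl$shared_with_next <- NA_integer_
  gl$wraps_origin <- NA
  gl$spacer_to_next[sp$upstream_idx] <- sp$spacer_bp
  gl$shared_with_next[sp$upstream_idx] <- sp$shared_bp
  gl$wraps_origin[sp$upstream_idx] <- sp$wraps_origin
  gl[order(first_start(features)), ]
}
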