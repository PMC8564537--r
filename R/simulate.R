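#' Background base probabilities from composition targets
#'
#' Closed-form split of target AT content and skews into four base
#' probabilities: with `at` the AT fraction and `s` the AT skew,
#' `P(A) = at (1 + s) / 2`, `P(T) = at (1 - s) / 2`, and likewise for G/C
#' from the GC fraction and GC skew. The expected composition of a sequence
#' drawn i.i.d. from these probabilities hits the targets exactly.
#'
#' @param at_content Target AT content, percent.
#' @param at_skew,gc_skew Target skews in `(-1, 1)`.
#' @return Named numeric vector of probabilities for `A`, `C`, `G`, `T`.
#' @export
base_probs <- function(at_content = 54.45, at_skew = 0, gc_skew = 0) {
  at <- at_content / 100
  gc <- 1 - at
  p <- c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
         G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-12)
  p
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Specify genes to plant in a simulated genome
#'
#' Helper building the `genes` argument of [simulate_genome()]. Each gene is
#' either placed explicitly (via a `segments` tibble) or auto-placed in free
#' intergenic space. PCG lengths must be multiples of 3; the planted coding
#' sequence starts with `init_codon`, ends with `term_codon`, and draws its
#' interior codons from `codon_profile`.
#'
#' @param gene Name.
#' @param category `"PCG"`, `"tRNA"`, `"rRNA"` or `"other"`.
#' @param strand `"J"` or `"N"`.
#' @param length Total length (ignored when `segments` given).
#' @param n_segments Number of segments for auto-placed genes (trans-spliced
#'   layouts use > 1).
#' @param segments Optional explicit tibble of `start`/`end` pairs.
#' @param init_codon,term_codon Planted terminal codons (PCGs).
#' @return One-row tibble suitable for `bind_rows()` into a gene plan.
#' @export
gene_spec <- function(gene, category = "PCG", strand = "J", length = 300,
                      n_segments = 1, segments = NULL,
                      init_codon = "ATG", term_codon = "TAA") {
  tibble(gene = gene, category = category, strand = strand,
         length = as.integer(if (is.null(segments)) length
                             else sum(segments$end - segments$start + 1)),
         n_segments = as.integer(if (is.null(segments)) n_segments
                                 else nrow(segments)),
         segments = list(segments),
         init_codon = init_codon, term_codon = term_codon)
}

#' Specify repeats to plant in a simulated genome
#'
#' @param unit Repeat unit (observed phase), e.g. `"AT"`.
#' @param copies Number of full copies.
#' @param start Optional explicit start; auto-placed otherwise.
#' @param in_gene Optional gene name; the repeat is stamped inside that
#'   gene's first sufficiently long segment (altering its sequence, as real
#'   in-gene microsatellites do).
#' @return One-row tibble for the `repeats` plan.
#' @export
repeat_spec <- function(unit, copies, start = NA, in_gene = NA) {
  tibble(unit = unit, copies = as.integer(copies),
         start = as.integer(start), in_gene = as.character(in_gene))
}

draw_cds <- function(length, init_codon, term_codon, codon_profile) {
  stopifnot(length %% 3 == 0, length >= 6)
  n_mid <- length / 3 - 2
  mid <- if (n_mid > 0) {
    sample(names(codon_profile), n_mid, replace = TRUE, prob = codon_profile)
  } else character()
  paste0(init_codon, paste(mid, collapse = ""), term_codon)
}

# choose non-colliding segment positions for auto-placed genes
place_segments <- function(length_bp, n_segments, occupied, genome_length,
                           gene, max_tries = 1000) {
  per <- diff(round(seq(0, length_bp, length.out = n_segments + 1)))
  for (try in seq_len(max_tries)) {
    starts <- sort(sample.int(genome_length - max(per) - 1, n_segments))
    segs <- tibble(start = as.integer(starts),
                   end = as.integer(starts + per - 1L))
    ok <- all(segs$end <= genome_length) &&
      (n_segments == 1 || all(segs$start[-1] > head(segs$end, -1) + 1)) &&
      !any(purrr::map_lgl(seq_len(nrow(segs)), function(i) {
        any(occupied$start <= segs$end[i] + 1L & occupied$end >= segs$start[i] - 1L)
      }))
    if (ok) return(segs)
  }
  abort(sprintf("could not place gene '%s' without collision after %d tries",
                gene, max_tries))
}

stamp <- function(sequence, start, what) {
  stopifnot(start >= 1, start + nchar(what) - 1 <= nchar(sequence))
  paste0(substr(sequence, 1, start - 1), what,
         substr(sequence, start + nchar(what), nchar(sequence)))
}

#' Simulate a mitogenome-like circular chromosome with known truth
#'
#' Generates a circle with (i) background drawn i.i.d. from base
#' probabilities solved from the target AT content and skews, (ii) planted
#' genes written at their segments (N-strand genes as the reverse complement
#' of their coding sequence, trans-spliced genes split across segments in
#' listed order), and (iii) repeats stamped last at reserved or requested
#' loci. Identical seed and plan give byte-identical output.
#'
#' @param length Circle length (bp).
#' @param genes Gene plan: `bind_rows()` of [gene_spec()] rows, or `NULL`.
#' @param repeats Repeat plan: rows of [repeat_spec()], or `NULL`.
#' @param at_content,at_skew,gc_skew Background composition targets
#'   (defaults emulate a plant mitogenome: AT around 54.5%, skews near 0).
#' @param codon_profile Named sampling probabilities over the 61 sense
#'   codons for PCG interiors (default uniform).
#' @param name Circle name.
#' @param seed Integer seed; all randomness is drawn under it.
#' @return List with `genome` ([mt_genome]), `features` (annotation tibble),
#'   and `truth` (the generator's bookkeeping: the plan, planted coding
#'   sequences, repeat records, base probabilities and seed).
#' @export
simulate_genome <- function(length, genes = NULL, repeats = NULL,
                            at_content = 54.45, at_skew = -0.0128,
                            gc_skew = -0.0241,
                            codon_profile = NULL, name = "sim", seed = 1) {
  probs <- base_probs(at_content, at_skew, gc_skew)
  if (is.null(codon_profile)) {
    sc <- sense_codons()
    codon_profile <- setNames(rep(1 / length(sc), length(sc)), sc)
  }
  withr::with_seed(seed, {
    seq <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
                 collapse = "")
    occupied <- tibble(start = integer(), end = integer())
    planted_genes <- NULL
    if (!is.null(genes) && nrow(genes) > 0) {
      segs_list <- vector("list", nrow(genes))
      cds_list <- character(nrow(genes))
      for (i in seq_len(nrow(genes))) {
        gi <- genes[i, ]
        segs <- gi$segments[[1]]
        if (is.null(segs)) {
          segs <- place_segments(gi$length, gi$n_segments, occupied, length,
                                 gi$gene)
        }
        occupied <- bind_rows(occupied, segs)
        cds <- if (gi$category == "PCG") {
          draw_cds(sum(segs$end - segs$start + 1), gi$init_codon,
                   gi$term_codon, codon_profile)
        } else {
          paste(sample(names(probs), sum(segs$end - segs$start + 1),
                       replace = TRUE, prob = probs), collapse = "")
        }
        forward <- if (gi$strand == "J") cds else revcomp(cds)
        offset <- 0L
        for (k in seq_len(nrow(segs))) {
          w <- segs$end[k] - segs$start[k] + 1L
          seq <- stamp(seq, segs$start[k],
                       substr(forward, offset + 1L, offset + w))
          offset <- offset + w
        }
        segs_list[[i]] <- segs
        cds_list[i] <- cds
      }
      planted_genes <- genes %>%
        mutate(segments = segs_list, coding_sequence = cds_list)
    }
    planted_repeats <- NULL
    if (!is.null(repeats) && nrow(repeats) > 0) {
      recs <- vector("list", nrow(repeats))
      for (i in seq_len(nrow(repeats))) {
        ri <- repeats[i, ]
        span <- nchar(ri$unit) * ri$copies
        start <- ri$start
        if (!is.na(ri$in_gene)) {
          j <- match(ri$in_gene, planted_genes$gene)
          if (is.na(j)) abort(sprintf("in_gene '%s' not planted", ri$in_gene))
          seg <- planted_genes$segments[[j]]
          seg <- seg[seg$end - seg$start + 1 >= span + 6, ][1, ]
          if (is.na(seg$start)) {
            abort(sprintf("no segment of '%s' can hold a %d bp repeat",
                          ri$in_gene, span))
          }
          room <- seg$end - seg$start + 1L - span - 6L
          start <- seg$start + 3L + if (room > 0) sample.int(room, 1) else 0L
        } else if (is.na(start)) {
          start <- place_segments(span, 1, occupied, length, ri$unit)$start
        }
        seq <- stamp(seq, start, strrep(ri$unit, ri$copies))
        occupied <- bind_rows(occupied,
                              tibble(start = start, end = start + span - 1L))
        recs[[i]] <- tibble(
          motif = canonical_motif(ri$unit), unit = ri$unit,
          unit_len = nchar(ri$unit), copies = ri$copies,
          start = as.integer(start), end = as.integer(start + span - 1L),
          span = as.integer(span), wraps_origin = FALSE,
          in_gene = ri$in_gene)
      }
      planted_repeats <- bind_rows(recs)
    }
    genome <- mt_genome(seq, name = name, circular = TRUE)
    # truth reflects the genome as built: an in-gene repeat stamped into a
    # planted gene becomes part of that gene's coding sequence
    if (!is.null(planted_genes)) {
      planted_genes$coding_sequence <- purrr::map_chr(
        seq_len(nrow(planted_genes)), function(i) {
          feature_sequence(genome, planted_genes$segments[[i]],
                           planted_genes$strand[i])
        })
    }
    features <- if (is.null(planted_genes)) {
      new_features(tibble(gene = character(), category = character(),
                          strand = character(), segments = list()),
                   genome_name = name, genome_length = length)
    } else {
      new_features(
        tibble(gene = planted_genes$gene,
               category = planted_genes$category,
               strand = planted_genes$strand,
               segments = planted_genes$segments,
               declared_length = planted_genes$length,
               init_codon = ifelse(planted_genes$category == "PCG",
                                   planted_genes$init_codon, NA_character_),
               term_codon = ifelse(planted_genes$category == "PCG",
                                   planted_genes$term_codon, NA_character_)),
        genome_name = name, genome_length = length)
    }
    list(genome = genome, features = features,
         truth = list(seed = seed, base_probs = probs,
                      at_content = at_content, at_skew = at_skew,
                      gc_skew = gc_skew, codon_profile = codon_profile,
                      planted_genes = planted_genes,
                      planted_repeats = planted_repeats))
  })
}

#' Simulate orthologous gene sets across species
#'
#' Draws one ancestral sequence per gene and mutates it independently per
#' species under a Jukes-Cantor-style per-site substitution draw: each site
#' is replaced, with probability `divergence`, by one of the three other
#' bases uniformly. Lengths are preserved.
#'
#' @param n_species Number of species (named `sp1`, `sp2`, ...).
#' @param gene_list Character vector of gene names, or a named integer
#'   vector of gene lengths (multiples of 3 for realism; default 300 bp per
#'   gene when unnamed).
#' @param divergence Per-site substitution probability in `[0, 0.75)`.
#' @param seed Integer seed.
#' @return Tibble `species`, `gene`, `sequence`; the ancestor is attached as
#'   attribute `ancestor` (named character vector).
#' @export
simulate_species_set <- function(n_species, gene_list, divergence = 0.1,
                                 seed = 1) {
  stopifnot(divergence >= 0, divergence < 0.75, n_species >= 1)
  lens <- if (is.numeric(gene_list)) gene_list else
    setNames(rep(300L, length(gene_list)), gene_list)
  withr::with_seed(seed, {
    ancestor <- purrr::map_chr(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    })
    species <- sprintf("sp%d", seq_len(n_species))
    rows <- purrr::map(species, function(sp) {
      tibble(species = sp, gene = names(ancestor),
             sequence = unname(purrr::map_chr(ancestor, mutate_seq,
                                              p = divergence)))
    })
    out <- bind_rows(rows)
    attr(out, "ancestor") <- ancestor
    out
  })
}

mutate_seq <- function(seq, p) {
  if (p == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < p
  if (any(hit)) {
    ch[hit] <- purrr::map_chr(ch[hit],
                              ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1))
  }
  paste(ch, collapse = "")
}
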