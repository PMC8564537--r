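feat_row <- function(gene, start, end, strand = "J", category = "PCG") {
  tibble::tibble(gene = gene, category = category, strand = strand,
                 segments = list(tibble::tibble(start = as.integer(start),
                                                end = as.integer(end))))
}

test_that("gene length is the exon sum, invariant under segment order", {
  f1 <- load_fixture(1)
  expect_equal(gene_length(f1[f1$gene == "nad7", ]), 1185L)
  f2 <- load_fixture(2)
  expect_equal(gene_length(f2[f2$gene == "orf954", ]), 954L)
  expect_equal(gene_length(feat_row("g", 1, 10)), 10L)
  scrambled <- feat_row("g", c(100, 10, 50), c(120, 15, 60))
  ordered <- feat_row("g", c(10, 50, 100), c(15, 60, 120))
  expect_equal(gene_length(scrambled), gene_length(ordered))
})

test_that("spacers reproduce the published overlap values", {
  f1 <- load_fixture(1)
  sp1 <- intergenic_spacers(f1)
  expect_equal(
    sp1$spacer_bp[sp1$upstream_gene == "rpl16" & sp1$downstream_gene == "rps3"],
    -110L)
  f2 <- load_fixture(2)
  sp2 <- intergenic_spacers(f2)
  expect_equal(
    sp2$spacer_bp[sp2$upstream_gene == "cox3" & sp2$downstream_gene == "sdh4"],
    -73L)
  expect_equal(
    sp2$spacer_bp[sp2$upstream_gene == "rps4"], -817L)
  # the nested tRNA's true sequence-level overlap is its own 65 bp span
  expect_equal(sp2$shared_bp[sp2$upstream_gene == "rps4"], 65L)
})

test_that("abutting genes have spacer zero and the wrap record closes the circle", {
  f <- dplyr::bind_rows(feat_row("a", 1, 10), feat_row("b", 11, 20))
  sp <- intergenic_spacers(f, genome_length = 30, circular = TRUE)
  expect_equal(sp$spacer_bp[sp$upstream_gene == "a"], 0L)
  wrap <- sp[sp$wraps_origin, ]
  expect_equal(wrap$upstream_gene, "b")
  expect_equal(wrap$spacer_bp, 30L - 20L + 1L - 1L)  # 1 + 30 - 20 - 1
  # published circle 1: tRNA-Arg back to tRNA-Thr
  wrap1 <- dplyr::filter(intergenic_spacers(load_fixture(1)), wraps_origin)
  expect_equal(wrap1$spacer_bp, 4421L + 109836L - 104467L - 1L)
})

test_that("spacer computation re-sorts and ignores input row order", {
  f1 <- load_fixture(1)
  shuffled <- f1[rev(seq_len(nrow(f1))), ]
  attr(shuffled, "genome_length") <- attr(f1, "genome_length")
  sp_a <- intergenic_spacers(f1)
  sp_b <- intergenic_spacers(shuffled, genome_length = 109836)
  expect_equal(sp_b[, c("upstream_gene", "downstream_gene", "spacer_bp")],
               sp_a[, c("upstream_gene", "downstream_gene", "spacer_bp")])
})

test_that("overlap pairs match the published per-circle counts", {
  ov1 <- overlap_pairs(load_fixture(1))
  expect_equal(nrow(ov1), 1)
  expect_equal(ov1$upstream_gene, "rpl16")
  expect_equal(ov1$overlap_bp, 110L)
  ov2 <- overlap_pairs(load_fixture(2))
  expect_equal(nrow(ov2), 2)
  expect_equal(sort(ov2$overlap_bp), c(73L, 817L))
  none <- dplyr::bind_rows(feat_row("a", 1, 10), feat_row("b", 20, 30))
  expect_equal(nrow(overlap_pairs(none, genome_length = 100)), 0)
})

test_that("coding fraction uses additive exon-sum accounting", {
  expect_equal(round(coding_fraction(45639, 414980)$percent, 1), 11.0)
  one <- feat_row("g", 1, 100)
  expect_equal(coding_fraction(one, 1000)$percent, 10)
  expect_error(coding_fraction(one, 0), "positive")
  genes <- dplyr::bind_rows(gene_spec("a", length = 300),
                            gene_spec("b", length = 450, strand = "N"))
  sim <- simulate_genome(10000, genes = genes, seed = 2)
  cf <- coding_fraction(sim$features, 10000)
  expect_equal(cf$coding_bp, sum(sim$truth$planted_genes$length))
  expect_equal(cf$percent, 100 * 750 / 10000)
})

test_that("spacers plus gene spans tile a circle of non-overlapping genes", {
  set.seed(21)
  starts <- sort(sample.int(900, 6))
  ends <- starts + 9L
  stopifnot(all(ends[-6] < starts[-1]))
  f <- dplyr::bind_rows(purrr::map(1:6, ~ feat_row(paste0("g", .x),
                                                   starts[.x], ends[.x])))
  sp <- intergenic_spacers(f, genome_length = 1000, circular = TRUE)
  expect_equal(sum(sp$spacer_bp) + sum(gene_length(f)), 1000L)
})

test_that("the spacer multiset is invariant under rotation of the circle", {
  f <- dplyr::bind_rows(feat_row("a", 100, 150), feat_row("b", 300, 420),
                        feat_row("c", 700, 850))
  rotate_feats <- function(f, shift, L) {
    f$segments <- purrr::map(f$segments, function(s) {
      s2 <- (s - 1 + shift) %% L + 1
      tibble::tibble(start = as.integer(s2$start), end = as.integer(s2$end))
    })
    f
  }
  sp0 <- sort(intergenic_spacers(f, genome_length = 1000)$spacer_bp)
  for (shift in c(50, 400)) {  # shifts that do not split any gene
    fr <- rotate_feats(f, shift, 1000)
    expect_equal(sort(intergenic_spacers(fr, genome_length = 1000)$spacer_bp),
                 sp0)
  }
})

test_that("gene_geometry joins lengths with spacers in genomic order", {
  g <- gene_geometry(load_fixture(1))
  expect_equal(g$gene[1], "tRNA-Thr")
  expect_equal(g$spacer_to_next[g$gene == "rpl16"], -110L)
  expect_equal(sum(is.na(g$spacer_to_next)), 0)
})
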