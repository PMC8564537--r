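test_that("CDS extraction honours strand and segment order", {
  g <- mt_genome("ATGAAATTTCCC", name = "t", circular = FALSE)
  f <- tibble::tibble(gene = "j", category = "PCG", strand = "J",
                      segments = list(tibble::tibble(start = 1L, end = 6L)))
  expect_equal(extract_cds(g, f)$cds, "ATGAAA")
  # an N-strand gene whose forward slice is TTACAT reads ATGTAA
  g2 <- mt_genome("CCTTACATCC", name = "t2")
  f2 <- tibble::tibble(gene = "n", category = "PCG", strand = "N",
                       segments = list(tibble::tibble(start = 3L, end = 8L)))
  expect_equal(extract_cds(g2, f2)$cds, "ATGTAA")
  f3 <- f2
  f3$segments <- list(tibble::tibble(start = c(3L, 30L), end = c(8L, 35L)))
  expect_error(extract_cds(g2, f3), "outside genome")
})

test_that("a trans-spliced N-strand gene yields its planted CDS exactly", {
  genes <- gene_spec("nadX", strand = "N", length = 300, n_segments = 4)
  sim <- simulate_genome(9000, genes = genes, seed = 13)
  got <- extract_cds(sim$genome, sim$features)
  expect_equal(got$cds, sim$truth$planted_genes$coding_sequence)
  expect_equal(nchar(got$cds), 300L)
})

test_that("codon counting chops in frame and books partial/ambiguous codons", {
  cc <- codon_counts("ATGTAA")
  expect_equal(sum(cc$count), 2L)
  expect_equal(cc$count[cc$codon == "ATG"], 1L)
  expect_equal(cc$count[cc$codon == "TAA"], 1L)
  expect_warning(cc2 <- codon_counts("ATGTAAC"), "dropped")
  expect_equal(attr(cc2, "dropped_nt"), 1L)
  expect_equal(attr(cc2, "total_codons"), 2L)
  cc3 <- codon_counts("ATGNNNTAA")
  expect_equal(attr(cc3, "ambiguous_codons"), 1L)
  expect_equal(attr(cc3, "total_codons"), 2L)
})

test_that("total codon conservation holds over a simulated CDS pool", {
  genes <- dplyr::bind_rows(purrr::map(1:5, ~ gene_spec(
    paste0("g", .x), length = 150 + 30 * .x,
    strand = c("J", "N")[.x %% 2 + 1])))
  sim <- simulate_genome(12000, genes = genes, seed = 4)
  pool <- extract_cds(sim$genome, sim$features)$cds
  cc <- codon_counts(pool)
  expect_equal(3L * (attr(cc, "total_codons") + attr(cc, "ambiguous_codons")) +
                 attr(cc, "dropped_nt"),
               sum(nchar(pool)))
})

test_that("RSCU follows the synonymous-family mean-ratio definition", {
  # Phe family TTT=3, TTC=1: hand arithmetic gives 1.5 and 0.5
  cds <- paste0("TTT", "TTT", "TTT", "TTC")
  r <- rscu(codon_counts(cds))
  expect_equal(r$rscu[r$codon == "TTT"], 1.5)
  expect_equal(r$rscu[r$codon == "TTC"], 0.5)
  # uniform usage in a family gives all 1
  r2 <- rscu(codon_counts(paste0("GGT", "GGC", "GGA", "GGG")))
  expect_equal(r2$rscu[r2$aa == "G"], rep(1, 4))
  # single-codon families are exactly 1 when observed
  r3 <- rscu(codon_counts("ATGTGG"))
  expect_equal(r3$rscu[r3$codon == "ATG"], 1)
  expect_equal(r3$rscu[r3$codon == "TGG"], 1)
  # unobserved families are undefined, not zero
  expect_true(all(is.na(r3$rscu[r3$aa == "K"])))
})

test_that("stop codons form one RSCU family unless excluded", {
  cds <- c("ATGTAA", "ATGTAA", "ATGTGA")
  r <- rscu(codon_counts(cds))
  stops <- r[r$aa == "*", ]
  expect_equal(sum(stops$rscu), 3)
  expect_equal(stops$rscu[stops$codon == "TAA"], 2 / 1)
  r2 <- rscu(codon_counts(cds), exclude_stops = TRUE)
  expect_false(any(r2$aa == "*"))
})

test_that("RSCU family sums equal family size for every observed family", {
  genes <- dplyr::bind_rows(purrr::map(1:3, ~ gene_spec(paste0("g", .x),
                                                        length = 600)))
  sim <- simulate_genome(8000, genes = genes, seed = 8)
  r <- rscu(codon_counts(extract_cds(sim$genome, sim$features)$cds))
  sums <- dplyr::summarise(dplyr::group_by(tidy(r), aa),
                           s = sum(rscu), n = dplyr::n(),
                           obs = sum(count) > 0)
  observed <- sums[sums$obs, ]
  expect_equal(observed$s, as.numeric(observed$n))
})

test_that("codon counts are identical for a gene planted on either strand", {
  genes_j <- gene_spec("g", strand = "J",
                       segments = tibble::tibble(start = 101L, end = 400L))
  genes_n <- gene_spec("g", strand = "N",
                       segments = tibble::tibble(start = 101L, end = 400L))
  sim_j <- simulate_genome(2000, genes = genes_j, seed = 6)
  sim_n <- simulate_genome(2000, genes = genes_n, seed = 6)
  cj <- codon_counts(extract_cds(sim_j$genome, sim_j$features)$cds)
  cn <- codon_counts(extract_cds(sim_n$genome, sim_n$features)$cds)
  expect_equal(cj$count, cn$count)
})

test_that("classification splits strictly at RSCU 1", {
  cc <- codon_counts(c("TTTTTTTTTTTC", "GGTGGCGGAGGG", "ATG"))
  cl <- classify_codons(cc)
  expect_equal(cl$class[cl$codon == "TTT"], "optimal")
  expect_equal(cl$class[cl$codon == "TTC"], "non_optimal")
  expect_equal(cl$class[cl$codon == "ATG"], "no_preference")
  expect_equal(cl$class[cl$aa == "G"], rep("no_preference", 4))
  expect_true(all(is.na(cl$class[cl$aa == "K"])))
})

test_that("increasing one codon's count raises its RSCU and lowers its synonyms'", {
  base <- codon_counts(c("TTTTTTTTC"))       # TTT=2, TTC=1
  more <- codon_counts(c("TTTTTTTTTTTC"))    # TTT=3, TTC=1
  rb <- rscu(base); rm_ <- rscu(more)
  expect_gt(rm_$rscu[rm_$codon == "TTT"], rb$rscu[rb$codon == "TTT"])
  expect_lt(rm_$rscu[rm_$codon == "TTC"], rb$rscu[rb$codon == "TTC"])
})

test_that("start/stop audit recovers planted codons and checks declarations", {
  genes <- dplyr::bind_rows(
    gene_spec("gA", length = 300, init_codon = "ATG", term_codon = "TAA"),
    gene_spec("gB", strand = "N", length = 150, init_codon = "ACG",
              term_codon = "TGA"))
  sim <- simulate_genome(6000, genes = genes, seed = 10)
  audit <- start_stop_audit(sim$genome, sim$features)
  expect_equal(audit$init_codon, c("ATG", "ACG"))
  expect_equal(audit$term_codon, c("TAA", "TGA"))
  expect_equal(audit$is_canonical_start, c(TRUE, FALSE))
  expect_true(all(audit$matches_declared))
  # a wrong declaration is flagged, not silently accepted
  f <- sim$features
  f$init_codon[1] <- "GTG"
  audit2 <- start_stop_audit(sim$genome, f)
  expect_false(audit2$matches_declared[1])
})

test_that("too-short CDS are flagged rather than audited", {
  g <- mt_genome("ATGCC", circular = FALSE)
  f <- tibble::tibble(gene = "stub", category = "PCG", strand = "J",
                      segments = list(tibble::tibble(start = 1L, end = 5L)))
  audit <- suppressWarnings(start_stop_audit(g, f))
  expect_false(audit$audited)
  expect_true(is.na(audit$init_codon))
})
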