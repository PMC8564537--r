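# fixed aperiodic background so planted repeats are the only structure;
# planted runs are wrapped in guard bases so they cannot extend into the pad
pad_pool <- withr::with_seed(
  20240101, paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                  collapse = ""))
pad <- function(n, offset = 0) substr(pad_pool, offset + 1, offset + n)

test_that("canonical motifs are the least rotation, phases retained", {
  expect_equal(canonical_motif(c("TA", "AT", "GAT", "A")),
               c("AT", "AT", "ATG", "A"))
})

test_that("runs below the MISA thresholds are not reported", {
  g <- mt_genome(paste0(pad(40), "C", strrep("G", 5), "C", pad(40)),
                 circular = FALSE)
  expect_equal(nrow(find_ssrs(g)), 0)
  g2 <- mt_genome(paste0(pad(40), "CC", strrep("AT", 5), "GG", pad(40)),
                  circular = FALSE)
  expect_equal(nrow(find_ssrs(g2)), 0)
})

test_that("planted SSRs are recovered once, at exact coordinates and extent", {
  g <- mt_genome(paste0(pad(38), "CC", strrep("AT", 8), "GG", pad(35),
                        "CC", strrep("T", 10), "GG", pad(40)),
                 circular = FALSE)
  ss <- find_ssrs(g)
  expect_equal(nrow(ss), 2)
  at <- ss[ss$unit_len == 2, ]
  expect_equal(at$motif, "AT")
  expect_equal(at$copies, 8L)
  expect_equal(at$start, 41L)
  expect_equal(at$end, 56L)
  tt <- ss[ss$unit_len == 1, ]
  expect_equal(tt$motif, "T")
  expect_equal(tt$copies, 10L)
  expect_equal(tt$span, 10L)
})

test_that("a repeat inside a planted gene is annotated with the gene name", {
  genes <- gene_spec("orf309", length = 309)
  reps <- repeat_spec("T", 10, in_gene = "orf309")
  sim <- simulate_genome(6000, genes = genes, repeats = reps, seed = 17)
  ss <- find_ssrs(sim$genome, features = sim$features)
  hit <- ss[!is.na(ss$in_gene), ]
  expect_true(nrow(hit) >= 1)
  expect_true("orf309" %in% hit$in_gene)
  planted <- sim$truth$planted_repeats
  expect_true(any(ss$motif == planted$motif & ss$copies >= planted$copies &
                    ss$start <= planted$end & ss$end >= planted$start))
})

test_that("a run crossing the origin is reported once and flagged", {
  # (A)12 split as 7 bases at the end and 5 at the start of the circle
  g <- mt_genome(paste0(strrep("A", 5), "C", pad(58), "C", strrep("A", 7)))
  ss <- find_ssrs(g)
  expect_equal(nrow(ss), 1)
  expect_true(ss$wraps_origin)
  expect_equal(ss$copies, 12L)
  expect_equal(ss$start, 66L)
  expect_equal(ss$end, 5L)
})

test_that("SSR multisets are rotation-invariant on a circle", {
  g <- mt_genome(paste0(pad(50), "GG", strrep("CT", 7), "GG", pad(51),
                        "CC", strrep("A", 11), "CC", pad(40)))
  key <- function(ss) dplyr::arrange(ss[, c("motif", "unit_len", "copies")],
                                     motif, copies)
  base <- key(find_ssrs(g))
  expect_equal(nrow(base), 2)
  for (shift in c(13, 101)) {
    expect_equal(key(find_ssrs(rotate_genome(g, shift))), base)
  }
})

test_that("reverse complement maps each SSR to its complement motif", {
  g <- mt_genome(paste0(pad(40), "CC", strrep("AG", 7), "CC", pad(41),
                        "GG", strrep("T", 12), "GG", pad(40)),
                 circular = FALSE)
  fwd <- find_ssrs(g)
  rev <- find_ssrs(mt_genome(revcomp(g$sequence), circular = FALSE))
  expect_equal(sort(canonical_motif(revcomp(fwd$unit))), sort(rev$motif))
  expect_equal(sort(fwd$copies), sort(rev$copies))
})

test_that("poly-purine runs are not double-reported at compound periods", {
  g <- mt_genome(paste0(pad(40), "C", strrep("A", 20), "C", pad(40)),
                 circular = FALSE)
  ss <- find_ssrs(g)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$unit_len, 1L)
  expect_equal(ss$copies, 20L)
})

test_that("adjacent runs form a compound group but stay separate records", {
  g <- mt_genome(paste0(pad(40), "C", strrep("A", 10), "C", strrep("TA", 8),
                        "GG", pad(40)), circular = FALSE)
  ss <- find_ssrs(g)
  expect_equal(nrow(ss), 2)
  expect_true(all(!is.na(ss$compound_group)))
  expect_equal(ss$compound_group[1], ss$compound_group[2])
})

test_that("minisatellite scanning finds exact-period repeats above threshold", {
  unit <- "ACGTTGCATTCAGTA"  # 15 bp, primitive
  g <- mt_genome(paste0(pad(50), strrep(unit, 4), pad(50, offset = 60)),
                 circular = FALSE)
  tr <- find_tandem_repeats(g)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$unit_len, 15L)
  expect_equal(tr$copies, 4L)
  expect_equal(tr$start, 51L)
  # 4 bp unit x 3 = 12 bp is below both unit range and min_total
  g2 <- mt_genome(paste0(pad(50), strrep("GCAT", 3), pad(50, offset = 60)),
                  circular = FALSE)
  expect_equal(nrow(find_tandem_repeats(g2)), 0)
  # a sequence with no exact period yields nothing
  expect_equal(nrow(find_tandem_repeats(mt_genome(pad(99), circular = FALSE),
                                        min_unit = 7, max_unit = 20)), 0)
})

test_that("repeat fraction reproduces the published figure from the census", {
  rf <- repeat_fraction(published_repeat_census(), 414980)
  expect_equal(rf$repeat_bp, 579L)
  expect_equal(round(rf$percent, 2), 0.14)
  expect_equal(repeat_fraction(published_repeat_census()[0, ], 100)$percent, 0)
  expect_error(repeat_fraction(published_repeat_census(), 0), "positive")
})

test_that("recall on planted threshold-meeting repeats is complete", {
  reps <- dplyr::bind_rows(
    repeat_spec("A", 12), repeat_spec("T", 10), repeat_spec("AT", 7),
    repeat_spec("GA", 6), repeat_spec("CTT", 5), repeat_spec("ACGTT", 5))
  sim <- simulate_genome(30000, repeats = reps, at_content = 50,
                         at_skew = 0, gc_skew = 0, seed = 23)
  found <- find_ssrs(sim$genome)
  truth <- sim$truth$planted_repeats
  # a maximal run may shift the reported full-copy window by up to one
  # unit relative to the planted phase; demand a same-motif overlapping
  # record with at least the planted copy number
  hit <- purrr::map_lgl(seq_len(nrow(truth)), function(i) {
    any(found$motif == truth$motif[i] &
          found$copies >= truth$copies[i] &
          found$start <= truth$end[i] & found$end >= truth$start[i])
  })
  expect_true(all(hit))
})

test_that("false positives on uniform random background are rare", {
  set.seed(77)
  s <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE), collapse = "")
  ss <- find_ssrs(mt_genome(s, circular = FALSE))
  # geometric-run bound: expected mononucleotide runs >= 10 is about
  # L * 4 * (1/4)^10 * (3/4) ~ 0.3; higher unit lengths contribute less
  expect_lte(nrow(ss), 3)
})
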