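mk_block <- function(occ, text) list(block_id = 1L, occ = occ, text = text)

occ2 <- data.frame(genome_id = c("g1", "g2"), seq_id = c("c1", "c1"),
                   start = c(0L, 0L), end = c(8L, 8L), strand = c("+", "+"),
                   src_size = c(8L, 8L), stringsAsFactors = FALSE)

test_that("relation counts column pairs, skipping gaps", {
  ab <- mk_block(occ2, c("GCACGTCC", "GCACTTCC"))
  expect_equal(length(relation_from_maf(list(ab))), 8L)

  occ2b <- occ2; occ2b$end[2] <- 7L
  ab2 <- mk_block(occ2b, c("GCACGTCC", "GCAC-TCC"))
  expect_equal(length(relation_from_maf(list(ab2))), 7L)

  occ3 <- data.frame(genome_id = c("g1", "g2", "g3"), seq_id = "c1",
                     start = 0L, end = 4L, strand = "+", src_size = 4L)
  ab3 <- mk_block(occ3, c("ACGT", "ACGT", "ACGT"))
  expect_equal(length(relation_from_maf(list(ab3))), 12L)  # C(3,2) * 4
})

test_that("relation matches the brute-force column-pair oracle on fuzz", {
  set.seed(19)
  for (rep in 1:15) {
    n <- sample(2:4, 1)
    gs <- toy_genomes(vapply(seq_len(n), function(i) rand_seq(sample(30:60, 1), 4),
                             character(1)), paste0("g", seq_len(n)))
    cg <- local({
      g <- comprehensive_dbg(gs, 5)
      compact_graph(g, find_junctions(g))
    })
    res <- find_collinear_blocks(cg, b = 20, m = 5)
    if (nrow(res$records) == 0L) next
    al <- align_all(res$records, gs)
    rel <- relation_from_maf(al)
    norm <- sort(vapply(rel$keys, function(k) {
      parts <- strsplit(k, "\n", fixed = TRUE)[[1]]
      a <- gsub("\r", " ", parts[1]); b <- gsub("\r", " ", parts[2])
      paste(min(a, b), max(a, b), parts[3] == "-")
    }, character(1), USE.NAMES = FALSE))
    oracle <- sort(unique(unlist(lapply(al, oracle_relation_pairs))))
    expect_equal(norm, oracle)
  }
})

test_that("recall and precision implement the set-difference formulas", {
  H <- homology_relation(c("g1", "g1"), "c1", c(1L, 2L), c("g2", "g2"), "c1", c(1L, 2L))
  A_eq <- H
  expect_equal(pair_recall(H, A_eq), 1)
  expect_equal(pair_precision(H, A_eq), 1)
  A_half <- homology_relation("g1", "c1", 1L, "g2", "c1", 1L)
  expect_equal(pair_recall(H, A_half), 0.5)
  # A superset of H: recall stays 1, precision drops
  A_sup <- homology_relation(c("g1", "g1", "g1", "g1"), "c1", 1:4,
                             c("g2", "g2", "g2", "g2"), "c1", 1:4)
  expect_equal(pair_recall(H, A_sup), 1)
  expect_equal(pair_precision(H, A_sup), 0.5)
  # |A| = 4, |A\H| = 1 -> 0.75
  H3 <- homology_relation(rep("g1", 3), "c1", 1:3, rep("g2", 3), "c1", 1:3)
  expect_equal(pair_precision(H3, A_sup), 0.75)
  # disjoint
  A_dis <- homology_relation("g1", "c1", 9L, "g2", "c1", 9L)
  expect_equal(pair_precision(H, A_dis), 0)
  expect_equal(pair_recall(H, A_dis), 0)
  expect_error(pair_recall(homology_relation(character(0), character(0),
                                             integer(0), character(0),
                                             character(0), integer(0)), A_eq),
               "undefined")
})

test_that("pairs match under joint strand flips", {
  a <- homology_relation("g1", "c1", 5L, "g2", "c1", 9L, flip = TRUE)
  b <- homology_relation("g2", "c1", 9L, "g1", "c1", 5L, flip = TRUE)
  expect_identical(a$keys, b$keys)
})

test_that("coverage counts covered positions once", {
  gs <- toy_genomes(c(rand_seq(100, 4), rand_seq(100, 4)), c("g1", "g2"))
  blocks <- block_set(c(1L, 1L), c("g1", "g2"), "c1", c(0L, 0L),
                      c(50L, 100L), c("+", "+"))
  expect_equal(block_coverage(blocks, gs), 150 / 200)
  expect_equal(block_coverage(blocks[0, ], gs), 0)
  one <- block_set(c(1L, 1L), c("g1", "g2"), "c1", c(0L, 0L), c(50L, 1L), c("+", "+"))
  expect_equal(block_coverage(one[one$genome_id == "g1", , drop = FALSE], gs), 0.25)
})

test_that("pi column formula", {
  expect_equal(pi_column(c("A", "A", "A", "A")), 0)
  expect_equal(pi_column(c("A", "A", "T")), 2 / 3)
  expect_equal(pi_column(c("A", "-", "T")), 1 / 3)
  expect_equal(pi_column(c("A", "C", "T")), 1)
  expect_error(pi_column("A"), "fewer than 2")
  # vectorised version agrees
  ab <- mk_block(occ2, c("GCACGTCC", "GCACTTCC"))
  pis <- pi_columns(list(ab))
  expect_equal(length(pis), 8L)
  expect_equal(sum(pis), 1)   # exactly one mismatching column
})

test_that("nucleotide identity counts matches over all columns", {
  expect_equal(nucleotide_identity("ACGTACGTAC", "ACGTACGTAC"), 1)
  expect_equal(nucleotide_identity("ACGTACGTAC", "ACTTACGT-C"), 0.8)
  expect_equal(nucleotide_identity("----", "ACGT"), 0)
  expect_error(nucleotide_identity("AC", "ACG"), "length")
})

test_that("identity bins are left-closed of width 5%", {
  b <- identity_bins(c(0.90, 0.949, 0.95, 1.0))
  expect_equal(sum(b), 4L)
  expect_equal(as.integer(b[["[0.9,0.95)"]]), 2L)
})

test_that("evaluate_alignment accepts relations, MAF and truth TSV", {
  sim <- simulate_genomes(sim_params(ancestor_length = 800, seed = 2,
                                     n_inversions = 0L, n_duplications = 0L))
  g <- comprehensive_dbg(sim$genomes, 11)
  cg <- compact_graph(g, find_junctions(g))
  res <- find_collinear_blocks(cg, 200, 50)
  al <- align_all(res$records, sim$genomes)
  maf <- withr::local_tempfile(fileext = ".maf")
  write_maf(al, maf)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(sim$truth, tsv)
  ev <- evaluate_alignment(maf, tsv)
  ev2 <- evaluate_alignment(al, truth_pairs(sim$truth))
  expect_equal(ev$recall, ev2$recall)
  expect_equal(ev$precision, ev2$precision)
  expect_gt(ev$recall, 0.5)
})
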