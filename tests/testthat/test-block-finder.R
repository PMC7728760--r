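fig <- worked_example_fixtures()

# small helper: full pipeline graph for a genome set
cgraph <- function(gs, k, a = 1e6, comprehensive = TRUE) {
  g <- if (comprehensive) comprehensive_dbg(gs, k) else dbg_build(gs, k)
  compact_graph(g, prune_abundance(find_junctions(g), g, a))
}

test_that("seed classes come in canonical lexicographic order and skip used ones", {
  cg <- cgraph(toy_genomes("GCACGTCC"), 2, comprehensive = FALSE)
  sc <- seed_classes(cg)
  expect_equal(sc$key, sort(sc$key, method = "radix"))
  used <- new_used(cg)
  used[cg$class_eids[[sc$key[1]]]] <- TRUE
  sc2 <- seed_classes(cg, used)
  expect_false(sc$key[1] %in% sc2$key)
})

test_that("the three-string worked example yields one block with three walks", {
  gs <- toy_genomes(fig$chain_trio, c("s1", "s2", "s3"))
  cg <- cgraph(gs, 2, comprehensive = FALSE)
  key <- seed_classes(cg)$key[seed_classes(cg)$u == "GC"][1]
  blk <- find_block_from_seed(cg, key, b = 4, m = 1)
  expect_equal(nrow(blk$walks), 3L)
  gids <- cg$contigs$genome_id[cg$oseq$contig_idx[blk$walks$oseq]]
  expect_setequal(gids, c("s1", "s2", "s3"))
  # each walk spans its whole sequence
  expect_true(all(blk$walks$length == 6))
  expect_gt(blk$score, 0)
})

test_that("a seed with a single occurrence cannot form a block", {
  cg <- cgraph(toy_genomes("GCACGTCC"), 2, comprehensive = FALSE)
  sc <- seed_classes(cg)
  expect_null(find_block_from_seed(cg, sc$key[1], b = 4, m = 1))
})

test_that("a planted exact repeat is recovered with score 2L", {
  set.seed(9)
  rep_seq <- rand_seq(120, 4)
  flank <- function(n) rand_seq(n, 4)
  gs <- toy_genomes(c(paste0(flank(80), rep_seq, flank(70)),
                      paste0(flank(60), rep_seq, flank(90))))
  cg <- cgraph(gs, 15)
  res <- find_collinear_blocks(cg, b = 200, m = 50)
  expect_gte(length(res$blocks), 1L)
  best <- res$blocks[[which.max(vapply(res$blocks, `[[`, numeric(1), "score"))]]
  # the repeat is 120 bp = 105 underlying edges at k=15; both walks
  # cover it exactly, no hanging ends: the score is L + L
  expect_equal(nrow(best$walks), 2L)
  expect_equal(best$score, sum(best$walks$length))
  expect_gte(max(best$walks$length), 120 - 15)
})

test_that("identical genomes are covered by blocks with one walk per genome", {
  set.seed(21)
  s <- rand_seq(600, 4)
  gs <- toy_genomes(c(s, s), c("g1", "g2"))
  cg <- cgraph(gs, 15)
  res <- find_collinear_blocks(cg, b = 200, m = 50)
  expect_equal(length(res$blocks), 1L)
  expect_equal(nrow(res$records), 2L)
  expect_gte(block_coverage(res$records, gs), 0.99)
  # every position covered at most once
  for (gid in c("g1", "g2")) {
    occ <- res$records[res$records$genome_id == gid, ]
    pos <- unlist(Map(seq, occ$start, occ$end - 1L))
    expect_false(anyDuplicated(pos) > 0)
  }
})

test_that("inputs without shared (k+1)-mers give no blocks", {
  gs <- toy_genomes(c("AAAAAAAAAA", "CCCCCCCCCC"))
  cg <- cgraph(gs, 4)
  res <- find_collinear_blocks(cg, b = 10, m = 1)
  expect_equal(length(res$blocks), 0L)
})

sim_small <- function(seed, L = 4000) {
  simulate_genomes(sim_params(ancestor_length = L, seed = seed,
                              inversion_length = c(300, 600),
                              duplication_length = c(120, 250)))
}

test_that("output walks are genomic, edge-disjoint, and scores recompute", {
  for (sd in c(5, 17)) {
    sim <- sim_small(sd)
    cg <- cgraph(sim$genomes, 15, a = 150)
    res <- find_collinear_blocks(cg, b = 200, m = 50)
    expect_gt(length(res$blocks), 0L)
    all_eids <- integer(0)
    for (blk in res$blocks) {
      # edge-disjointness including strand twins
      ids <- c(blk$eids, cg$edges$twin[blk$eids])
      ids <- ids[!is.na(ids)]
      expect_false(any(duplicated(ids)))
      expect_false(any(ids %in% all_eids))
      all_eids <- c(all_eids, ids)
      # genomicity: each walk's vertices re-spell from the input sequence
      for (r in seq_len(nrow(blk$walks))) {
        o <- blk$walks$oseq[r]
        ids_w <- cg$o_eids[[as.character(o)]][blk$walks$from[r]:blk$walks$to[r]]
        offs <- cg$edges$off[ids_w]
        kmers <- substring(cg$oseq$seq[o], offs + 1L, offs + cg$k)
        vw <- blk$walk_vws[[r]]
        expect_equal(kmers, vw$vertices[-length(vw$vertices)])
      }
      # stored score equals the exact rescoring
      expect_equal(score_block(blk$carrying_path, blk$walk_vws, 50, 200),
                   blk$score)
      expect_gt(blk$score, 0)
      expect_true(all(blk$walks$length >= 50))
    }
  }
})

test_that("results are independent of the seed batch size", {
  sim <- sim_small(3)
  cg <- cgraph(sim$genomes, 15, a = 150)
  r1 <- find_collinear_blocks(cg, 200, 50, batch_size = 1)
  r64 <- find_collinear_blocks(cg, 200, 50, batch_size = 64)
  expect_identical(r1$records, r64$records)
})

test_that("reverse-complementing the input mirrors the blocks", {
  sim <- sim_small(13)
  gs <- sim$genomes
  cg <- cgraph(gs, 15, a = 150)
  r1 <- find_collinear_blocks(cg, 200, 50)
  gs2 <- gs
  gs2$sequence <- revcomp(gs$sequence)
  cg2 <- cgraph(gs2, 15, a = 150)
  r2 <- find_collinear_blocks(cg2, 200, 50)
  L <- gs$length[match(paste(r2$records$genome_id, r2$records$seq_id),
                       paste(gs$genome_id, gs$seq_id))]
  mirrored <- data.frame(genome_id = r2$records$genome_id,
                         seq_id = r2$records$seq_id,
                         start = L - r2$records$end, end = L - r2$records$start,
                         strand = ifelse(r2$records$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$genome_id, d$seq_id, d$start, d$end, d$strand))
  expect_identical(key(mirrored), key(r1$records))
})

test_that("block records never overlap and lie within their contigs", {
  sim <- sim_small(29)
  cg <- cgraph(sim$genomes, 15, a = 150)
  rec <- find_collinear_blocks(cg, 200, 50)$records
  expect_true(all(rec$start >= 0))
  len <- sim$genomes$length[match(paste(rec$genome_id, rec$seq_id),
                                  paste(sim$genomes$genome_id, sim$genomes$seq_id))]
  expect_true(all(rec$end <= len))
  for (ct in unique(paste(rec$genome_id, rec$seq_id))) {
    d <- rec[paste(rec$genome_id, rec$seq_id) == ct, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1L) expect_true(all(d$start[-1L] >= d$end[-nrow(d)]))
  }
  cnt <- table(rec$block_id)
  expect_true(all(cnt >= 2L))
})
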