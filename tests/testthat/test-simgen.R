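test_that("zero-rate parameters reproduce the ancestor exactly", {
  p <- sim_params(n_genomes = 3, ancestor_length = 500, substitution_rate = 0,
                  indel_rate = 0, n_inversions = 0L, n_duplications = 0L, seed = 4)
  sim <- simulate_genomes(p)
  expect_true(all(sim$genomes$sequence == sim$ancestor))
  H <- truth_pairs(sim$truth)
  expect_equal(length(H), choose(3, 2) * 500)
})

test_that("simulation is byte-identical under a fixed seed", {
  p <- sim_params(ancestor_length = 2000, seed = 123)
  s1 <- simulate_genomes(p)
  s2 <- simulate_genomes(p)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth$maps, s2$truth$maps)
  s3 <- simulate_genomes(sim_params(ancestor_length = 2000, seed = 124))
  expect_false(identical(s1$genomes$sequence, s3$genomes$sequence))
})

test_that("pairwise mismatch fraction matches the two-branch expectation", {
  p <- sim_params(n_genomes = 2, ancestor_length = 10000, substitution_rate = 0.02,
                  indel_rate = 0, n_inversions = 0L, n_duplications = 0L, seed = 8)
  sim <- simulate_genomes(p)
  a <- strsplit(sim$genomes$sequence[1], "")[[1]]
  b <- strsplit(sim$genomes$sequence[2], "")[[1]]
  obs <- mean(a != b)
  s <- 0.02
  exp_mismatch <- 2 * s * (1 - s) + s * s * (2 / 3)  # both mutated, differently
  sd3 <- 3 * sqrt(exp_mismatch * (1 - exp_mismatch) / 10000)
  expect_lt(abs(obs - exp_mismatch), sd3)
})

test_that("inversions flip strand inside the segment and nowhere else", {
  p <- sim_params(n_genomes = 1, ancestor_length = 1000, substitution_rate = 0,
                  indel_rate = 0, n_inversions = 1L, inversion_length = c(100L, 100L),
                  n_duplications = 0L, seed = 5)
  sim <- simulate_genomes(p)
  m <- sim$truth$maps[[1]]
  flipped <- which(m$strand == -1L)
  expect_equal(length(flipped), 100L)
  expect_equal(flipped, seq(min(flipped), max(flipped)))
  # inverted segment: positions map to reversed ancestral coordinates
  expect_equal(m$anc[flipped], rev(seq(m$anc[max(flipped)], m$anc[min(flipped)])))
  # sequence agrees with the reverse complement of the ancestral slice
  fpos <- m$pos[flipped]
  seg <- substr(sim$genomes$sequence[1], min(fpos) + 1L, max(fpos) + 1L)
  anc_slice <- substr(sim$ancestor, min(m$anc[flipped]) + 1L, max(m$anc[flipped]) + 1L)
  expect_equal(seg, revcomp(anc_slice))
})

test_that("duplications create within-genome pairs linked through the ancestor", {
  p <- sim_params(n_genomes = 1, ancestor_length = 1000, substitution_rate = 0,
                  indel_rate = 0, n_inversions = 0L, n_duplications = 1L,
                  duplication_length = c(80L, 80L), seed = 6)
  sim <- simulate_genomes(p)
  expect_equal(sim$genomes$length, 1080L)
  H <- truth_pairs(sim$truth)
  expect_equal(length(H), 80L)   # one within-genome pair per duplicated position
})

test_that("truth relation is symmetric and transitive through the ancestor", {
  sim <- simulate_genomes(sim_params(n_genomes = 3, ancestor_length = 300,
                                     substitution_rate = 0.05, seed = 9,
                                     n_inversions = 0L, n_duplications = 0L,
                                     indel_rate = 0.01))
  maps <- sim$truth$maps
  # pick ancestral positions present in all three genomes; their pairwise
  # links must compose
  common <- Reduce(intersect, lapply(maps, function(m) m$anc[!is.na(m$anc)]))
  expect_gt(length(common), 200)
  H <- truth_pairs(sim$truth)
  a <- common[1]
  pos <- vapply(maps, function(m) m$pos[match(a, m$anc)], integer(1))
  k12 <- homology_relation("g1", "chr1", pos[1], "g2", "chr1", pos[2])$keys
  k13 <- homology_relation("g1", "chr1", pos[1], "g3", "chr1", pos[3])$keys
  k23 <- homology_relation("g2", "chr1", pos[2], "g3", "chr1", pos[3])$keys
  expect_true(all(c(k12, k13, k23) %in% H$keys))
})

test_that("parameter validation rejects rates outside [0, 1]", {
  expect_error(sim_params(substitution_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_params(indel_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_params(ancestor_length = 0), "positive")
})

test_that("fixtures carry the expected toy inputs", {
  fx <- worked_example_fixtures()
  expect_equal(unname(fx$chain_pair), c("GCACGTCC", "GCACTTCC"))
  expect_equal(unname(fx$chain_trio[3]), "CACGTTCC")
  # hanging_ends realises |p| = 4 with unit hanging ends (checked in lcb-core tests)
  expect_equal(fx$hanging_ends$k, 2L)
})

test_that("truth TSV round-trips", {
  sim <- simulate_genomes(sim_params(ancestor_length = 400, seed = 10))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(sim$truth, tsv)
  H1 <- truth_pairs(sim$truth)
  H2 <- read_truth_tsv(tsv)
  expect_setequal(H1$keys, H2$keys)
})
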