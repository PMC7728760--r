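fig <- worked_example_fixtures()

test_that("b-extension respects the bound, fragment ends, and used edges", {
  gs <- toy_genomes("GCACGTCCAA")
  g <- dbg_build(gs, 2)
  cg <- compact_graph(g, dbg_vertices(g))   # unit-length edges
  w <- collinear_walk(cg, "s1", "c1", "+", 1, 2)
  ext <- b_extension(cg, w, b = 3)
  expect_equal(c(ext$from, ext$to), c(3L, 5L))          # length exactly b
  # near the end: truncated
  w2 <- collinear_walk(cg, "s1", "c1", "+", 1, 6)
  ext2 <- b_extension(cg, w2, b = 200)
  expect_equal(c(ext2$from, ext2$to), c(7L, 8L))
  # next edge used: empty
  used <- new_used(cg)
  used[cg$o_eids[["1"]][3]] <- TRUE
  expect_null(b_extension(cg, w, b = 3, used = used))
  # used edge inside: truncated immediately before it
  used2 <- new_used(cg)
  used2[cg$o_eids[["1"]][5]] <- TRUE
  ext3 <- b_extension(cg, w, b = 5, used = used2)
  expect_equal(c(ext3$from, ext3$to), c(3L, 4L))
})

test_that("bubble predicate matches the worked example", {
  g <- dbg_build(toy_genomes(fig$chain_pair, c("s1", "s2")), 2)
  # AC -> CG -> GT -> TC versus AC -> CT -> TT -> TC
  x <- vertex_walk(c("AC", "CG", "GT", "TC"))
  y <- vertex_walk(c("AC", "CT", "TT", "TC"))
  expect_true(is_bubble(x, y, 4))
  expect_false(is_bubble(x, y, 2))          # side longer than b
  # two distinct parallel edges form a bubble
  cg <- compact_graph(g, dbg_vertices(g))
  e1 <- as_vertex_walk(cg, collinear_walk(cg, "s1", "c1", "+", 1, 1))
  e2 <- as_vertex_walk(cg, collinear_walk(cg, "s2", "c1", "+", 1, 1))
  expect_true(is_bubble(e1, e2, 4))
  # a walk does not form a bubble with its own occurrence
  expect_false(is_bubble(e1, e1, 4))
  # shared interior vertex disqualifies
  expect_false(is_bubble(vertex_walk(c("AA", "CC", "TT")),
                         vertex_walk(c("AA", "CC", "GG", "TT")), 9))
})

test_that("chain decomposition recovers the four-bubble chain of the two-string example", {
  g <- dbg_build(toy_genomes(fig$chain_pair, c("s1", "s2")), 2)
  pa <- contig_walk(g, "s1", "c1")
  p <- contig_walk(g, "s2", "c1")
  d <- decompose_chain(pa, p, b = 4)
  expect_equal(nrow(d$bubbles), 4L)
  expect_equal(d$q1_len, 0)
  expect_equal(d$q3_len, 0)
  expect_equal(d$q2_len, walk_length(pa))
  # every reported bubble satisfies the bubble predicate
  for (r in seq_len(nrow(d$bubbles))) {
    bx <- vertex_walk(pa$vertices[d$bubbles$pa_from[r]:d$bubbles$pa_to[r]],
                      pa$lengths[d$bubbles$pa_from[r]:(d$bubbles$pa_to[r] - 1L)])
    by <- vertex_walk(p$vertices[d$bubbles$p_from[r]:d$bubbles$p_to[r]],
                      p$lengths[d$bubbles$p_from[r]:(d$bubbles$p_to[r] - 1L)])
    expect_true(is_bubble(bx, by, 4))
  }
})

test_that("a walk equal to the carrying path is a chain of parallel-edge bubbles", {
  g <- dbg_build(toy_genomes("GCACGT"), 2)
  pa <- contig_walk(g, "s1", "c1")
  d <- decompose_chain(pa, pa, b = 1)
  expect_equal(d$q1_len, 0)
  expect_equal(d$q3_len, 0)
  expect_equal(nrow(d$bubbles), walk_length(pa))
})

test_that("the hanging-end configuration splits as q1 = q3 = 1", {
  gs <- toy_genomes(c(fig$hanging_ends$carrier, fig$hanging_ends$walk), c("a", "b"))
  g <- dbg_build(gs, fig$hanging_ends$k)
  pa <- contig_walk(g, "a", "c1")
  p <- contig_walk(g, "b", "c1")
  d <- decompose_chain(pa, p, b = 4)
  expect_equal(c(d$q1_len, d$q2_len, d$q3_len), c(1, 4, 1))
})

test_that("chain decomposition agrees with the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:250) {
    s1 <- rand_seq(sample(6:16, 1), alpha = sample(2:3, 1))
    s2 <- rand_seq(sample(6:16, 1), alpha = sample(2:3, 1))
    g <- dbg_build(toy_genomes(c(s1, s2)), 2)
    pa <- path_prefix(contig_walk(g, "s1", "c1"))
    if (is.null(pa)) next
    p <- contig_walk(g, "s2", "c1")
    b <- sample(1:4, 1)
    d <- decompose_chain(pa, p, b)
    o <- oracle_decompose(pa, p, b)
    expect_equal(c(d$q1_len, d$q2_len, d$q3_len), unname(o),
                 info = paste(s1, s2, b))
  }
})

test_that("score function implements all three cases", {
  gs <- toy_genomes(c(fig$hanging_ends$carrier, fig$hanging_ends$walk), c("a", "b"))
  g <- dbg_build(gs, 2)
  pa <- contig_walk(g, "a", "c1")
  p <- contig_walk(g, "b", "c1")
  expect_equal(score_walk(pa, p, m = 4, b = 4), 0)     # 4 - (1+1)^2
  expect_equal(score_walk(pa, p, m = 5, b = 4), 0)     # |p| < m
  expect_equal(score_walk(pa, p, m = 4, b = 1), 0)     # parallel chain shrinks, ends grow
  # direct evaluation: |p| = 10, q1 = 0, q3 = 2 -> 10 - 4 = 6
  pa2 <- vertex_walk(paste0("v", 1:13))
  p2 <- vertex_walk(paste0("v", 1:11))
  expect_equal(score_walk(pa2, p2, m = 5, b = 5), 6)
  # hanging end beyond b: -Inf
  pa3 <- vertex_walk(paste0("v", 1:10))
  p3 <- vertex_walk(paste0("v", 8:10))   # chain at the end, q1 = 7 > b
  expect_equal(score_walk(pa3, p3, m = 2, b = 3), -Inf)
})

test_that("block score is the sum of walk scores", {
  gs <- toy_genomes(c(fig$hanging_ends$carrier, fig$hanging_ends$walk), c("a", "b"))
  g <- dbg_build(gs, 2)
  pa <- contig_walk(g, "a", "c1")
  p <- contig_walk(g, "b", "c1")
  expect_equal(score_block(pa, list(), 4, 4), 0)
  expect_equal(score_block(pa, list(p, p), 4, 4), 0)   # 0 + 0
  expect_equal(score_block(pa, list(p, p), 5, 4), 0)   # all below m
  expect_equal(score_block(pa, list(pa, p), 4, 4), walk_length(pa) + 0)
})

test_that("score is monotone non-increasing in the hanging-end total for |p| >= m", {
  # vary the chain position along a fixed carrying path: hanging ends
  # grow, score never increases
  # fixed walk, growing carrying path: q1 + q3 grows, score never increases
  p <- vertex_walk(paste0("v", 1:5))
  scores <- vapply(6:12, function(n) {
    score_walk(vertex_walk(paste0("v", 1:n)), p, m = 2, b = 20)
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("strand antisymmetry: mirrored decomposition mirrors the split", {
  set.seed(55)
  for (rep in 1:30) {
    s1 <- rand_seq(sample(8:16, 1), 3)
    s2 <- rand_seq(sample(8:16, 1), 3)
    g <- dbg_build(toy_genomes(c(s1, s2)), 2)
    pa <- path_prefix(contig_walk(g, "s1", "c1"))
    if (is.null(pa)) next
    p <- contig_walk(g, "s2", "c1")
    rcw <- function(w) vertex_walk(rev(revcomp(w$vertices)), rev(w$lengths))
    d <- decompose_chain(pa, p, 3)
    dr <- decompose_chain(rcw(pa), rcw(p), 3)
    # the maximal chain length is mirror-invariant, and so is the total
    # hanging-end mass; the individual ends swap up to tie resolution
    expect_equal(dr$q2_len, d$q2_len)
    expect_equal(dr$q1_len + dr$q3_len, d$q1_len + d$q3_len)
  }
})
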