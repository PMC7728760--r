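# Synthetic closely related genomes with exact homology ground truth.
#
# A uniform i.i.d. ACGT ancestor evolves independently into each genome
# (star phylogeny): per-site substitutions, short geometric indels, then
# inversions (reverse complement in place; truth pairs become
# strand-flipped) and tandem segmental duplications (the copy inherits
# the ancestral links). Every surviving position keeps a link to the
# ancestral position it descends from; the truth relation is the set of
# position pairs sharing an ancestral position.

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters of the genome simulator
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: three genomes of 50 kbp at an evolutionary distance of
#' 0.02 substitutions per site to their common ancestor, with sparse
#' short indels, one inversion and one tandem duplication per genome.
#'
#' @param n_genomes number of genomes (independent children of the
#'   ancestor).
#' @param ancestor_length ancestor length in bp.
#' @param substitution_rate per-site substitution probability on each
#'   ancestor-to-leaf branch (subs/site to the MRCA).
#' @param indel_rate expected indel events per site.
#' @param indel_mean_length mean indel length (geometric).
#' @param n_inversions inversions per genome.
#' @param inversion_length length range (bp) of an inversion.
#' @param n_duplications tandem duplications per genome.
#' @param duplication_length length range (bp) of a duplication.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_genomes = 3L, ancestor_length = 50000L,
                       substitution_rate = 0.02, indel_rate = 0.002,
                       indel_mean_length = 3, n_inversions = 1L,
                       inversion_length = c(2000L, 5000L),
                       n_duplications = 1L,
                       duplication_length = c(500L, 1500L), seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1) stop_param("substitution rate must be in [0, 1]")
  if (indel_rate < 0 || indel_rate > 1) stop_param("indel rate must be in [0, 1]")
  if (ancestor_length < 1 || n_genomes < 1) stop_param("sizes must be positive")
  if (indel_mean_length < 1) stop_param("indel mean length must be >= 1")
  p <- list(n_genomes = as.integer(n_genomes),
            ancestor_length = as.integer(ancestor_length),
            substitution_rate = substitution_rate, indel_rate = indel_rate,
            indel_mean_length = indel_mean_length,
            n_inversions = as.integer(n_inversions),
            inversion_length = as.integer(inversion_length),
            n_duplications = as.integer(n_duplications),
            duplication_length = as.integer(duplication_length),
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

# uniform draw from an inclusive integer range (safe for degenerate ranges)
sample_range <- function(r) r[1L] + sample.int(r[2L] - r[1L] + 1L, 1L) - 1L

evolve_one <- function(anc, p) {
  L <- length(anc)
  chars <- anc
  amap <- seq_len(L) - 1L          # ancestral position, NA for inserted
  strand <- rep.int(1L, L)
  # substitutions: uniform over the three alternatives
  mut <- which(runif(L) < p$substitution_rate)
  if (length(mut)) {
    cur <- match(chars[mut], BASES)
    chars[mut] <- BASES[((cur - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L]
  }
  # indels
  n_ind <- rbinom(1L, L, p$indel_rate)
  for (i in seq_len(n_ind)) {
    cur <- length(chars)
    len <- rgeom(1L, 1 / p$indel_mean_length) + 1L
    if (runif(1L) < 0.5 && cur > len + 1L) {       # deletion
      s <- sample.int(cur - len + 1L, 1L)
      keep <- setdiff(seq_len(cur), s:(s + len - 1L))
      chars <- chars[keep]; amap <- amap[keep]; strand <- strand[keep]
    } else {                                        # insertion
      s <- sample.int(cur + 1L, 1L) - 1L           # insert after position s
      ins <- sample(BASES, len, replace = TRUE)
      idx <- if (s == 0L) integer(0) else seq_len(s)
      chars <- c(chars[idx], ins, chars[setdiff(seq_along(chars), idx)])
      amap <- c(amap[idx], rep.int(NA_integer_, len), amap[setdiff(seq_along(amap), idx)])
      strand <- c(strand[idx], rep.int(1L, len), strand[setdiff(seq_along(strand), idx)])
    }
  }
  # inversions: reverse complement in place
  for (i in seq_len(p$n_inversions)) {
    cur <- length(chars)
    len <- sample_range(p$inversion_length)
    if (cur <= len + 2L) next
    s <- sample.int(cur - len + 1L, 1L)
    rng <- s:(s + len - 1L)
    chars[rng] <- rev(unname(COMP[chars[rng]]))
    amap[rng] <- rev(amap[rng])
    strand[rng] <- -rev(strand[rng])
  }
  # tandem duplications: copy inherits the ancestral links
  for (i in seq_len(p$n_duplications)) {
    cur <- length(chars)
    len <- sample_range(p$duplication_length)
    if (cur <= len + 2L) next
    s <- sample.int(cur - len + 1L, 1L)
    rng <- s:(s + len - 1L)
    pre <- seq_len(s + len - 1L)
    post <- setdiff(seq_along(chars), pre)
    chars <- c(chars[pre], chars[rng], chars[post])
    amap <- c(amap[pre], amap[rng], amap[post])
    strand <- c(strand[pre], strand[rng], strand[post])
  }
  list(chars = chars, amap = amap, strand = strand)
}

#' Simulate closely related genomes with ground truth
#'
#' @param params a [sim_params()].
#' @return list with `genomes` (a [genome_set()], one contig `chr1` per
#'   genome `g1`, `g2`, ...), `truth` (a `truth_map`: per-genome tables
#'   of position, ancestral position and strand), and `ancestor`.
#' @export
simulate_genomes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  run_with_seed(params$seed, {
    anc <- sample(BASES, params$ancestor_length, replace = TRUE)
    gs <- lapply(seq_len(params$n_genomes), function(i) evolve_one(anc, params))
    genomes <- genome_set(vapply(gs, function(g) paste(g$chars, collapse = ""), character(1)),
                          genome_id = paste0("g", seq_len(params$n_genomes)),
                          seq_id = rep("chr1", params$n_genomes))
    maps <- lapply(seq_len(params$n_genomes), function(i) {
      data.frame(genome_id = paste0("g", i), seq_id = "chr1",
                 pos = seq_along(gs[[i]]$chars) - 1L,
                 anc = gs[[i]]$amap, strand = gs[[i]]$strand,
                 stringsAsFactors = FALSE)
    })
    truth <- list(maps = maps, params = params)
    class(truth) <- "truth_map"
    list(genomes = genomes, truth = truth,
         ancestor = paste(anc, collapse = ""))
  })
}

#' Homology relation of a simulated truth map
#'
#' All pairs of positions (across genomes and within a genome, e.g.
#' duplication copies) descending from the same ancestral position;
#' pairs whose strands disagree are flagged as flipped.
#'
#' @param truth a `truth_map` from [simulate_genomes()].
#' @return a [homology_relation()].
#' @export
truth_pairs <- function(truth) {
  dt <- data.table::rbindlist(truth$maps)
  dt <- dt[!is.na(dt$anc)]
  dt$idx <- seq_len(nrow(dt))
  m <- merge(dt, dt, by = "anc", allow.cartesian = TRUE)
  m <- m[m$idx.x < m$idx.y]
  homology_relation(m$genome_id.x, m$seq_id.x, m$pos.x,
                    m$genome_id.y, m$seq_id.y, m$pos.y,
                    m$strand.x != m$strand.y)
}

#' Write / read a truth relation as TSV
#'
#' Columns: genome1 seq1 pos1 genome2 seq2 pos2 flip (0-based positions,
#' `flip` = 1 for opposite-strand pairs).
#'
#' @param truth a `truth_map` from [simulate_genomes()].
#' @param path output file.
#' @export
write_truth_tsv <- function(truth, path) {
  dt <- data.table::rbindlist(truth$maps)
  dt <- dt[!is.na(dt$anc)]
  dt$idx <- seq_len(nrow(dt))
  m <- merge(dt, dt, by = "anc", allow.cartesian = TRUE)
  m <- m[m$idx.x < m$idx.y]
  out <- data.frame(genome1 = m$genome_id.x, seq1 = m$seq_id.x, pos1 = m$pos.x,
                    genome2 = m$genome_id.y, seq2 = m$seq_id.y, pos2 = m$pos.y,
                    flip = as.integer(m$strand.x != m$strand.y))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @return `read_truth_tsv`: a [homology_relation()].
#' @export
read_truth_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  homology_relation(d$genome1, d$seq1, d$pos1, d$genome2, d$seq2, d$pos2,
                    d$flip == 1L)
}

#' Worked-example fixtures
#'
#' The toy inputs used throughout the documentation and tests: the
#' two-string bubble-chain example, its three-string extension, and a
#' carrying-path/walk pair whose score evaluates to
#' `4 - (1 + 1)^2 = 0`.
#'
#' @return named list: `chain_pair` (two 8 bp strings forming a chain of
#'   four bubbles at k = 2), `chain_trio` (the same plus a third string),
#'   `hanging_ends` (list with `carrier`, `walk`, `k`: a length-4 walk
#'   whose chain with the carrying path leaves hanging ends of length 1
#'   on each side).
#' @export
worked_example_fixtures <- function() {
  list(chain_pair = c(s1 = "GCACGTCC", s2 = "GCACTTCC"),
       chain_trio = c(s1 = "GCACGTCC", s2 = "GCACTTCC", s3 = "CACGTTCC"),
       hanging_ends = list(carrier = "AACGTGCT", walk = "ACGTGC", k = 2L))
}
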