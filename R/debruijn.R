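# Ordinary and comprehensive de Bruijn graphs.
#
# Vertices are k-mers; every occurrence of a (k+1)-mer contributes one
# directed edge from its length-k prefix to its length-k suffix, so
# parallel edges are exactly the occurrences of one (k+1)-mer. Runs of
# non-ACGT characters split contigs into fragments that no k-mer spans.

# Split [0, L) into maximal ACGT runs of a contig sequence.
acgt_runs <- function(seq) {
  n <- nchar(seq)
  ok <- strsplit(seq, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T")
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Build a de Bruijn graph from a genome set
#'
#' @param genomes a [genome_set()].
#' @param k k-mer size (vertices are k-mers, edges (k+1)-mer occurrences).
#' @param comprehensive if `TRUE`, build the double-stranded graph: the
#'   union of the graphs of every contig and its reverse complement, so
#'   that every edge occurrence has a reverse-complement twin.
#' @return an object of class `dbg`.
#' @export
#' @examples
#' g <- dbg_build(genome_set(c(c1 = "GCACGTCC")), k = 2)
#' nrow(dbg_edges(g))  # 6 edge occurrences
dbg_build <- function(genomes, k, comprehensive = FALSE) {
  if (!is.numeric(k) || k < 2) stop_param("k must be an integer >= 2")
  k <- as.integer(k)
  contigs <- data.frame(contig_idx = seq_len(nrow(genomes)),
                        genome_id = genomes$genome_id, seq_id = genomes$seq_id,
                        length = genomes$length, stringsAsFactors = FALSE)
  strands <- if (comprehensive) c("+", "-") else "+"
  oseq <- do.call(rbind, lapply(contigs$contig_idx, function(ci) {
    data.frame(contig_idx = ci, strand = strands, stringsAsFactors = FALSE)
  }))
  oseq$oseq <- seq_len(nrow(oseq))
  oseq$seq <- ifelse(oseq$strand == "+", genomes$sequence[oseq$contig_idx],
                     revcomp(genomes$sequence[oseq$contig_idx]))
  oseq$len <- nchar(oseq$seq)

  frag_list <- lapply(seq_len(nrow(oseq)), function(o) {
    runs <- acgt_runs(oseq$seq[o])
    if (nrow(runs) == 0L) return(NULL)
    cbind(oseq = o, runs)
  })
  frags <- do.call(rbind, frag_list)
  if (is.null(frags)) frags <- data.frame(oseq = integer(0), start = integer(0), end = integer(0))
  frags$frag <- seq_len(nrow(frags))

  occ_list <- lapply(seq_len(nrow(frags)), function(f) {
    s <- frags$start[f]; e <- frags$end[f]; o <- frags$oseq[f]
    if (e - s < k + 1L) return(NULL)
    offs <- s:(e - k - 1L)
    data.frame(oseq = o, frag = frags$frag[f], off = offs,
               kp1 = substr_at(oseq$seq[o], offs, k + 1L), stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, occ_list)
  if (is.null(occ)) {
    occ <- data.frame(oseq = integer(0), frag = integer(0), off = integer(0),
                      kp1 = character(0), stringsAsFactors = FALSE)
    warning("no contig fragment longer than k: graph has no edges")
  }
  rownames(occ) <- NULL
  g <- list(k = k, comprehensive = comprehensive, genomes = genomes,
            contigs = contigs, oseq = oseq, frags = frags, occ = occ)
  class(g) <- "dbg"
  g
}

#' Build the comprehensive (double-stranded) de Bruijn graph
#'
#' Shorthand for `dbg_build(genomes, k, comprehensive = TRUE)`.
#'
#' @inheritParams dbg_build
#' @return a `dbg` with reverse-complement twin edges.
#' @export
comprehensive_dbg <- function(genomes, k) dbg_build(genomes, k, comprehensive = TRUE)

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k=%d, %d contig(s), %d edge occurrence(s), %d vertex k-mer(s)%s\n",
              x$k, nrow(x$contigs), nrow(x$occ), length(dbg_vertices(x)),
              if (x$comprehensive) ", double-stranded" else ""))
  invisible(x)
}

#' Edge occurrences of a de Bruijn graph
#'
#' @param g a `dbg`.
#' @return data.frame with one row per edge occurrence: `genome_id`,
#'   `seq_id`, `strand`, `offset` (0-based, strand-local start of the
#'   (k+1)-mer) and `kp1mer`.
#' @export
dbg_edges <- function(g) {
  o <- g$occ
  data.frame(genome_id = g$contigs$genome_id[g$oseq$contig_idx[o$oseq]],
             seq_id = g$contigs$seq_id[g$oseq$contig_idx[o$oseq]],
             strand = g$oseq$strand[o$oseq], offset = o$off, kp1mer = o$kp1,
             stringsAsFactors = FALSE)
}

#' Vertex set (distinct k-mers) of a de Bruijn graph
#'
#' @param g a `dbg`.
#' @return character vector of k-mers.
#' @export
dbg_vertices <- function(g) {
  k <- g$k
  vs <- lapply(seq_len(nrow(g$frags)), function(f) {
    s <- g$frags$start[f]; e <- g$frags$end[f]; o <- g$frags$oseq[f]
    if (e - s < k) return(character(0))
    substr_at(g$oseq$seq[o], s:(e - k), k)
  })
  sort(unique(unlist(vs)), method = "radix")
}

# Resolve a user-facing edge spec to an occurrence row index.
edge_row <- function(g, genome_id, seq_id, offset, strand = "+") {
  ci <- which(g$contigs$genome_id == genome_id & g$contigs$seq_id == seq_id)
  if (length(ci) != 1L) stop_param("unknown contig ", genome_id, ".", seq_id)
  o <- which(g$oseq$contig_idx == ci & g$oseq$strand == strand)
  if (length(o) != 1L) stop_param("strand ", strand, " not present in this graph")
  r <- which(g$occ$oseq == o & g$occ$off == offset)
  if (length(r) != 1L) stop_param("no edge at offset ", offset, " of ", genome_id,
                                  ".", seq_id, " (", strand, ")")
  r
}

#' Look up one graph edge by its location
#'
#' @param g a `dbg`.
#' @param genome_id,seq_id contig.
#' @param offset 0-based start of the (k+1)-mer on the given strand.
#' @param strand "+" or "-".
#' @return an object of class `graph_edge`.
#' @export
dbg_edge <- function(g, genome_id, seq_id, offset, strand = "+") {
  r <- edge_row(g, genome_id, seq_id, offset, strand)
  e <- list(genome_id = genome_id, seq_id = seq_id, strand = strand,
            offset = g$occ$off[r], kp1mer = g$occ$kp1[r])
  class(e) <- "graph_edge"
  e
}

#' Successor of an edge along its sequence
#'
#' Returns the edge occurrence at `pos + 1` of the same sequence and
#' strand, or `NULL` at a fragment end (a successor does not always
#' exist).
#'
#' @param g a `dbg`.
#' @param e a `graph_edge` belonging to `g`.
#' @return a `graph_edge` or `NULL`.
#' @export
next_edge <- function(g, e) {
  r <- edge_row(g, e$genome_id, e$seq_id, e$offset, e$strand)
  if (g$occ$kp1[r] != e$kp1mer) stop_param("edge does not belong to this graph")
  r2 <- which(g$occ$oseq == g$occ$oseq[r] & g$occ$off == e$offset + 1L)
  if (length(r2) == 0L || g$occ$frag[r2] != g$occ$frag[r]) return(NULL)
  dbg_edge(g, e$genome_id, e$seq_id, e$offset + 1L, e$strand)
}

#' Reverse-complement twin of an edge
#'
#' Defined only on comprehensive graphs: the occurrence of the
#' reverse-complement (k+1)-mer at the mirrored location on the opposite
#' strand. `twin_edge(twin_edge(e))` is `e`.
#'
#' @param g a comprehensive `dbg`.
#' @param e a `graph_edge`.
#' @return a `graph_edge`.
#' @export
twin_edge <- function(g, e) {
  if (!g$comprehensive) stop_param("twin edges exist only in a comprehensive graph")
  r <- edge_row(g, e$genome_id, e$seq_id, e$offset, e$strand)
  ci <- g$oseq$contig_idx[g$occ$oseq[r]]
  L <- g$contigs$length[ci]
  dbg_edge(g, e$genome_id, e$seq_id, L - g$k - 1L - e$offset,
           if (e$strand == "+") "-" else "+")
}

#' Find junction k-mers
#'
#' A k-mer is a junction iff it has at least two distinct out-neighbours
#' or at least two distinct in-neighbours. The first and last k-mer of
#' every fragment are additionally retained as sentinel junctions so that
#' every genomic position lies on some compacted edge; self-loops count
#' their vertex once as a neighbour.
#'
#' @param g a `dbg`.
#' @return character vector of junction k-mers, with the sentinel-only
#'   ones listed in `attr(, "sentinels")`.
#' @export
find_junctions <- function(g) {
  k <- g$k
  kp1u <- unique(g$occ$kp1)
  u <- substr(kp1u, 1L, k)
  v <- substr(kp1u, 2L, k + 1L)
  outdeg <- table(u)
  indeg <- table(v)
  branching <- sort(unique(c(names(outdeg)[outdeg >= 2L], names(indeg)[indeg >= 2L])),
                    method = "radix")
  sent <- unlist(lapply(seq_len(nrow(g$frags)), function(f) {
    s <- g$frags$start[f]; e <- g$frags$end[f]; o <- g$frags$oseq[f]
    if (e - s < k) return(character(0))
    c(substr_at(g$oseq$seq[o], s, k), substr_at(g$oseq$seq[o], e - k, k))
  }))
  sent <- sort(setdiff(unique(sent), branching), method = "radix")
  out <- c(branching, sent)
  attr(out, "sentinels") <- sent
  out
}

#' Remove high-abundance junctions
#'
#' Junction k-mers whose total occurrence count (summed over both strands
#' present in the graph) exceeds the abundance pruning parameter `a` are
#' removed before the compacted edge set is constructed; sentinel
#' junctions are retained. This tames high-copy repeats at the cost of
#' not recovering blocks with multiplicity above `a`.
#'
#' @param junctions output of [find_junctions()].
#' @param g the `dbg` the junctions came from.
#' @param a abundance threshold (keep k-mers occurring at most `a` times).
#' @return pruned junction k-mer vector (sentinel attribute preserved).
#' @export
prune_abundance <- function(junctions, g, a) {
  if (!is.numeric(a) || a < 1) stop_param("abundance threshold a must be >= 1")
  k <- g$k
  counts <- integer(length(junctions))
  names(counts) <- junctions
  for (f in seq_len(nrow(g$frags))) {
    s <- g$frags$start[f]; e <- g$frags$end[f]; o <- g$frags$oseq[f]
    if (e - s < k) next
    kv <- substr_at(g$oseq$seq[o], s:(e - k), k)
    kv <- kv[kv %in% junctions]
    if (length(kv)) {
      tb <- table(kv)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
  }
  sent <- attr(junctions, "sentinels")
  keep <- junctions[counts <= a | junctions %in% sent]
  out <- as.character(keep)
  attr(out, "sentinels") <- sent
  out
}
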