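# Walks, bubbles, chains and the collinearity score.
#
# All lengths are measured in underlying (k+1)-mer edges, also on the
# compacted graph where an edge contributes its stored step length. A
# bubble is a pair of walks with common endpoints, no other shared
# vertices, and both sides at most b edges long; a chain is a series of
# bubbles in which each bubble properly continues the previous one.

#' Construct an abstract vertex walk
#'
#' A walk through the graph given as its vertex sequence plus the length
#' (in underlying edges) of each step. Carrying paths and collinear walks
#' are both represented this way for the chain calculus.
#'
#' @param vertices character vector of vertex labels (k-mers), length >= 2.
#' @param lengths positive step lengths, one per edge (default all 1).
#' @param labels edge labels, one per edge: two edges are parallel iff
#'   their labels are equal (on the compacted graph the label is the
#'   spelled sequence). Default: endpoint pair, which identifies the
#'   (k+1)-mer on an ordinary graph.
#' @return object of class `vertex_walk`.
#' @export
vertex_walk <- function(vertices, lengths = NULL, labels = NULL) {
  vertices <- as.character(vertices)
  if (length(vertices) < 2L) stop_param("a walk needs at least one edge")
  if (is.null(lengths)) lengths <- rep(1, length(vertices) - 1L)
  if (length(lengths) != length(vertices) - 1L) {
    stop_param("need one length per edge")
  }
  if (any(lengths < 1)) stop_param("step lengths must be positive")
  if (is.null(labels)) {
    labels <- paste(vertices[-length(vertices)], vertices[-1L], sep = ">")
  }
  if (length(labels) != length(vertices) - 1L) stop_param("need one label per edge")
  w <- list(vertices = vertices, lengths = as.numeric(lengths),
            labels = as.character(labels))
  class(w) <- "vertex_walk"
  w
}

#' Total length of a vertex walk, in underlying edges
#' @param w a `vertex_walk`.
#' @return numeric scalar.
#' @export
walk_length <- function(w) sum(w$lengths)

## ---------------------------------------------------------------------------
## Graph-bound collinear walks

# Oriented-sequence index for a (genome, seq, strand) triple.
oseq_index <- function(cg, genome_id, seq_id, strand = "+") {
  ci <- which(cg$contigs$genome_id == genome_id & cg$contigs$seq_id == seq_id)
  if (length(ci) != 1L) stop_param("unknown contig ", genome_id, ".", seq_id)
  o <- which(cg$oseq$contig_idx == ci & cg$oseq$strand == strand)
  if (length(o) != 1L) stop_param("strand ", strand, " not in graph")
  o
}

#' A genomic walk on the compacted graph
#'
#' Identified by an oriented sequence and a half-open-free 1-based range
#' `[from, to]` of consecutive compacted-edge indices along it.
#'
#' @param cg a `cdbg`.
#' @param genome_id,seq_id,strand the oriented sequence.
#' @param from,to first and last compacted-edge index (1-based, inclusive).
#' @return object of class `collinear_walk`.
#' @export
collinear_walk <- function(cg, genome_id, seq_id, strand, from, to) {
  o <- oseq_index(cg, genome_id, seq_id, strand)
  ids <- cg$o_eids[[as.character(o)]]
  if (is.null(ids) || from < 1L || to > length(ids) || from > to) {
    stop_param("edge range [", from, ", ", to, "] outside oriented sequence")
  }
  fr <- cg$o_frag[[as.character(o)]]
  if (fr[from] != fr[to]) stop_param("walk crosses a fragment boundary (not genomic)")
  w <- list(oseq = o, from = as.integer(from), to = as.integer(to))
  class(w) <- "collinear_walk"
  w
}

#' Convert a graph-bound walk to an abstract vertex walk
#'
#' @param cg a `cdbg`.
#' @param w a `collinear_walk`.
#' @return a [vertex_walk()] carrying the occurrence as an attribute.
#' @export
as_vertex_walk <- function(cg, w) {
  ids <- cg$o_eids[[as.character(w$oseq)]][w$from:w$to]
  vw <- vertex_walk(c(cg$vertices[cg$edges$u[ids[1L]]], cg$vertices[cg$edges$v[ids]]),
                    cg$edges$len[ids], cg$edges$spelled[ids])
  attr(vw, "occurrence") <- c(oseq = w$oseq, from = w$from, to = w$to)
  vw
}

#' Vertex walk of a whole contig in an ordinary de Bruijn graph
#'
#' Convenience for worked examples: the genomic walk spelled by (the
#' first fragment of) a contig, with unit step lengths.
#'
#' @param g a `dbg`.
#' @param genome_id,seq_id contig.
#' @param strand "+" or "-".
#' @return a [vertex_walk()].
#' @export
contig_walk <- function(g, genome_id, seq_id, strand = "+") {
  ci <- which(g$contigs$genome_id == genome_id & g$contigs$seq_id == seq_id)
  if (length(ci) != 1L) stop_param("unknown contig ", genome_id, ".", seq_id)
  o <- which(g$oseq$contig_idx == ci & g$oseq$strand == strand)
  rows <- which(g$occ$oseq == o & g$occ$frag == g$occ$frag[g$occ$oseq == o][1L])
  if (length(rows) == 0L) stop_param("contig has no edges at this k")
  kp1 <- g$occ$kp1[rows]
  vertex_walk(c(substr(kp1[1L], 1L, g$k), substr(kp1, 2L, g$k + 1L)),
              labels = kp1)
}

#' Fresh used-edge mark store for a compacted graph
#'
#' @param cg a `cdbg`.
#' @return logical vector, one flag per compacted edge occurrence.
#' @export
new_used <- function(cg) logical(nrow(cg$edges))

#' b-extension of a genomic walk
#'
#' The longest genomic walk starting at the successor of the walk's last
#' edge, of total length at most `b` underlying edges, truncated at the
#' fragment end and immediately before the first used edge. Empty
#' (`NULL`) if no such edge exists. The first compacted edge is always
#' taken even when its step length alone exceeds `b`: a single compacted
#' edge stands for a non-branching run of the ordinary graph and must
#' remain traversable.
#'
#' @param cg a `cdbg`.
#' @param walk a [collinear_walk()].
#' @param b maximum extension length in underlying edges.
#' @param used optional used-edge store from [new_used()].
#' @return a `collinear_walk` or `NULL`.
#' @export
b_extension <- function(cg, walk, b, used = NULL) {
  if (b < 1) stop_param("b must be >= 1")
  o <- as.character(walk$oseq)
  ids <- cg$o_eids[[o]]
  fr <- cg$o_frag[[o]]
  cum <- cg$o_cum[[o]]
  n <- length(ids)
  i <- walk$to + 1L
  if (i > n || fr[i] != fr[walk$to]) return(NULL)
  if (!is.null(used) && used[ids[i]]) return(NULL)
  j <- i
  while (j + 1L <= n && fr[j + 1L] == fr[i] &&
         cum[j + 2L] - cum[i] <= b &&
         (is.null(used) || !used[ids[j + 1L]])) {
    j <- j + 1L
  }
  out <- list(oseq = walk$oseq, from = i, to = j)
  class(out) <- "collinear_walk"
  out
}

## ---------------------------------------------------------------------------
## Bubbles

# Shared-vertex rule for a bubble: besides the common endpoints, the two
# sides share nothing; in particular neither side's interior may contain
# an endpoint occurrence of the other side.
bubble_interiors_ok <- function(vx, vy) {
  nx <- length(vx); ny <- length(vy)
  ix <- if (nx > 2L) vx[2L:(nx - 1L)] else character(0)
  iy <- if (ny > 2L) vy[2L:(ny - 1L)] else character(0)
  !any(ix %in% vy) && !any(iy %in% vx)
}

#' Do two walks form a bubble?
#'
#' True iff the walks share their start and end vertices, share no other
#' vertex, and both sides are at most `b` underlying edges long. Two
#' distinct parallel edges form a bubble; a walk never forms a bubble
#' with itself (the same occurrence).
#'
#' @param x,y walks: [vertex_walk()]s (possibly from [as_vertex_walk()]).
#' @param b maximum side length in underlying edges.
#' @return logical.
#' @export
is_bubble <- function(x, y, b) {
  ox <- attr(x, "occurrence"); oy <- attr(y, "occurrence")
  if (!is.null(ox) && !is.null(oy) && identical(ox, oy)) return(FALSE)
  vx <- x$vertices; vy <- y$vertices
  if (vx[1L] != vy[1L] || vx[length(vx)] != vy[length(vy)]) return(FALSE)
  if (walk_length(x) > b || walk_length(y) > b) return(FALSE)
  bubble_interiors_ok(vx, vy)
}

## ---------------------------------------------------------------------------
## Chain decomposition

#' Decompose a carrying path against a collinear walk
#'
#' Finds the longest contiguous subpath q2 of the carrying path such that
#' q2 and a subwalk of `p` form a chain of bubbles (each side of every
#' bubble at most `b` edges), and returns the induced split
#' `pa = q1 q2 q3`. Lengths are in underlying edges. Among equally long
#' candidates the split minimising `q1` wins. If no chain exists the
#' split is `(0, 0, |pa|)`.
#'
#' @param pa carrying path as a [vertex_walk()]; must visit each vertex
#'   at most once.
#' @param p collinear walk as a [vertex_walk()].
#' @param b maximum bubble side length.
#' @return list with `q1_len`, `q2_len`, `q3_len`, `pa_range` and
#'   `p_range` (vertex-index ranges of the chain, or `NULL`), and
#'   `bubbles` (data.frame of vertex-index spans, one row per bubble).
#' @export
decompose_chain <- function(pa, p, b) {
  V <- pa$vertices
  if (anyDuplicated(V)) stop_param("carrying path must visit each vertex at most once")
  U <- p$vertices
  cum <- c(0, cumsum(pa$lengths))
  pcv <- c(0, cumsum(p$lengths))
  total_pa <- cum[length(cum)]

  mh <- match(U, V)
  ss <- which(!is.na(mh))
  hh <- mh[ss]
  np <- length(ss)
  empty <- list(q1_len = 0, q2_len = 0, q3_len = total_pa,
                pa_range = NULL, p_range = NULL,
                bubbles = data.frame(pa_from = integer(0), pa_to = integer(0),
                                     p_from = integer(0), p_to = integer(0)))
  if (np < 2L) return(empty)

  pal <- pa$labels; pll <- p$labels
  best <- rep(Inf, np)    # minimal chain-start cum over chains ending at pair t
  par <- integer(np)      # predecessor pair (>0: extend its chain; <0: chain starts there)
  for (t2 in 2L:np) {
    j2 <- hh[t2]; s2 <- ss[t2]
    run_max <- -Inf       # max h among intermediate pairs with h <= j2
    bv <- Inf; bp <- 0L
    for (i in (t2 - 1L):1L) {
      h1 <- hh[i]; s1 <- ss[i]
      # two parallel edges always form a bubble, whatever their length
      prl <- h1 == j2 - 1L && s1 == s2 - 1L && pal[h1] == pll[s1]
      if (!prl && pcv[s2] - pcv[s1] > b) break
      if (h1 < j2 && h1 > run_max &&
          (prl || (cum[j2] - cum[h1] <= b && pcv[s2] - pcv[s1] <= b))) {
        cand <- min(best[i], cum[h1])
        if (cand < bv) {
          bv <- cand
          bp <- if (best[i] <= cum[h1]) i else -i
        }
      }
      if (h1 <= j2) run_max <- max(run_max, h1)
    }
    if (bv < Inf) { best[t2] <- bv; par[t2] <- bp }
  }

  done <- which(is.finite(best))
  if (length(done) == 0L) return(empty)
  len <- cum[hh[done]] - best[done]
  pick <- done[order(-len, best[done], hh[done])][1L]

  # backtrack the match-point sequence
  chain <- pick
  cur <- pick
  while (par[cur] > 0L) { cur <- par[cur]; chain <- c(cur, chain) }
  chain <- c(abs(par[cur]), chain)

  i1 <- hh[chain[1L]]; j1 <- hh[chain[length(chain)]]
  nb <- length(chain) - 1L
  bubbles <- data.frame(pa_from = hh[chain[-length(chain)]], pa_to = hh[chain[-1L]],
                        p_from = ss[chain[-length(chain)]], p_to = ss[chain[-1L]])
  list(q1_len = cum[i1], q2_len = cum[j1] - cum[i1], q3_len = total_pa - cum[j1],
       pa_range = c(i1, j1), p_range = c(ss[chain[1L]], ss[chain[length(chain)]]),
       bubbles = bubbles)
}

## ---------------------------------------------------------------------------
## Scoring

#' Collinearity score of one walk against a carrying path
#'
#' The score is 0 if the walk is shorter than `m`; otherwise it is
#' `|p| - (|q1| + |q3|)^2` where q1 and q3 are the hanging ends of the
#' carrying path left uncovered by the longest chain, provided both
#' hanging ends are at most `b` edges; walks whose hanging ends exceed
#' `b` score `-Inf`.
#'
#' @param pa carrying path ([vertex_walk()]).
#' @param p collinear walk ([vertex_walk()]).
#' @param m minimum walk length in underlying edges.
#' @param b maximum bubble side length.
#' @return numeric scalar (possibly `-Inf`).
#' @export
score_walk <- function(pa, p, m, b) {
  if (m < 1) stop_param("m must be >= 1")
  if (b < 1) stop_param("b must be >= 1")
  lp <- walk_length(p)
  if (lp < m) return(0)
  d <- decompose_chain(pa, p, b)
  if (d$q1_len > b || d$q3_len > b) return(-Inf)
  lp - (d$q1_len + d$q3_len)^2
}

#' Collinearity score of a collinear block
#'
#' Sum of [score_walk()] over the walks of the block, for the given
#' carrying path.
#'
#' @param pa carrying path ([vertex_walk()]).
#' @param walks list of [vertex_walk()]s (pairwise edge-disjoint).
#' @param m,b as in [score_walk()].
#' @return numeric scalar.
#' @export
score_block <- function(pa, walks, m, b) {
  if (length(walks) == 0L) return(0)
  sum(vapply(walks, function(p) score_walk(pa, p, m, b), numeric(1)))
}
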