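# Compacted de Bruijn graph: junction k-mers plus, per sequence, the
# ordered junction occurrences; each pair of consecutive occurrences is a
# compacted edge annotated with its spelled sequence and its length in
# (k+1)-mer steps. Lengths everywhere downstream are measured in
# underlying (k+1)-mer edges, so a compacted edge of length L stands for
# L ordinary edges.

#' Compact a de Bruijn graph over a junction set
#'
#' Produces per-sequence ordered junction occurrences and the compacted
#' edge set. Fragment end positions are always included as junction
#' occurrences (sentinels), so decompressing the compacted edges of a
#' fragment reproduces it exactly. Two compacted edges belong to the same
#' class iff they spell the same sequence; for double-stranded graphs the
#' canonical class key is the lexicographic minimum of the spelled
#' sequence and its reverse complement, and every edge occurrence knows
#' its reverse-complement twin.
#'
#' @param g a `dbg` (ordinary or comprehensive).
#' @param junctions junction k-mer set from [find_junctions()], possibly
#'   pruned with [prune_abundance()]. Use `dbg_vertices(g)` to reproduce
#'   the ordinary graph.
#' @return an object of class `cdbg`.
#' @export
compact_graph <- function(g, junctions) {
  k <- g$k
  sent_needed <- unlist(lapply(seq_len(nrow(g$frags)), function(f) {
    s <- g$frags$start[f]; e <- g$frags$end[f]; o <- g$frags$oseq[f]
    if (e - s < k) return(character(0))
    c(substr_at(g$oseq$seq[o], s, k), substr_at(g$oseq$seq[o], e - k, k))
  }))
  if (!all(unique(sent_needed) %in% junctions) && is.null(attr(junctions, "sentinels"))) {
    # sentinels must be present one way or another; positional sentinels
    # below guarantee representability, but a junction set that lost its
    # sentinel attribute and its end k-mers is a consistency error
    missing <- setdiff(unique(sent_needed), junctions)
    if (length(missing)) stop_param("junction set is missing sentinel k-mers: ",
                                    paste(head(missing, 3L), collapse = ", "))
  }

  jocc_list <- vector("list", nrow(g$frags))
  for (f in seq_len(nrow(g$frags))) {
    s <- g$frags$start[f]; e <- g$frags$end[f]; o <- g$frags$oseq[f]
    if (e - s < k) next
    offs <- s:(e - k)
    kv <- substr_at(g$oseq$seq[o], offs, k)
    sel <- kv %in% junctions
    sel[1L] <- TRUE; sel[length(sel)] <- TRUE   # positional sentinels
    jocc_list[[f]] <- data.frame(oseq = o, frag = f, off = offs[sel],
                                 kmer = kv[sel], stringsAsFactors = FALSE)
  }
  jocc <- do.call(rbind, jocc_list)
  if (is.null(jocc)) stop_param("graph has no fragment of length >= k")
  rownames(jocc) <- NULL

  vertices <- sort(unique(jocc$kmer), method = "radix")
  jocc$vid <- match(jocc$kmer, vertices)
  rc_vid <- match(revcomp(vertices), vertices)   # NA if rc not a junction

  # compacted edges: consecutive junction occurrences within a fragment
  n <- nrow(jocc)
  same_frag <- jocc$frag[-1L] == jocc$frag[-n]
  from <- which(same_frag)
  edges <- data.frame(oseq = jocc$oseq[from], frag = jocc$frag[from],
                      off = jocc$off[from], u = jocc$vid[from],
                      v = jocc$vid[from + 1L],
                      len = jocc$off[from + 1L] - jocc$off[from])
  edges$spelled <- substr_at(g$oseq$seq[edges$oseq], edges$off, edges$len + k)
  if (g$comprehensive) {
    rcsp <- revcomp(edges$spelled)
    edges$canon <- ifelse(edges$spelled <= rcsp, edges$spelled, rcsp)
    edges$dir <- edges$spelled == edges$canon
  } else {
    edges$canon <- edges$spelled
    edges$dir <- TRUE
  }
  edges <- edges[order(edges$oseq, edges$off, method = "radix"), , drop = FALSE]
  edges$eid <- seq_len(nrow(edges))
  idx <- unlist(lapply(split(edges$eid, edges$oseq), seq_along), use.names = FALSE)
  edges$idx <- idx

  # reverse-complement twins (comprehensive graphs only)
  if (g$comprehensive) {
    ci <- g$oseq$contig_idx[edges$oseq]
    L <- g$contigs$length[ci]
    twin_oseq <- ifelse(g$oseq$strand[edges$oseq] == "+", edges$oseq + 1L, edges$oseq - 1L)
    twin_off <- L - k - edges$off - edges$len
    edges$twin <- match(paste(twin_oseq, twin_off), paste(edges$oseq, edges$off))
  } else {
    edges$twin <- NA_integer_
  }

  # deterministic occurrence order, invariant under global reverse
  # complementation of the input: each physical edge is located by the
  # strand-local offset of its canonical-direction record (which reading
  # direction is canonical does not change when the input is mirrored)
  ci <- g$oseq$contig_idx[edges$oseq]
  canon_off <- ifelse(edges$dir | is.na(edges$twin), edges$off, edges$off[edges$twin])
  edges$rank <- order(order(ci, canon_off, !edges$dir, edges$off, method = "radix"))

  o_eids <- split(edges$eid, edges$oseq)
  o_cum <- lapply(o_eids, function(ids) c(0, cumsum(edges$len[ids])))
  o_frag <- lapply(o_eids, function(ids) edges$frag[ids])
  in_eids <- lapply(split(edges$eid, edges$v),
                    function(ids) ids[order(edges$rank[ids])])
  in_vids <- as.integer(names(in_eids))
  in_map <- vector("list", length(vertices))
  in_map[in_vids] <- in_eids

  class_keys <- sort(unique(edges$canon), method = "radix")
  class_eids <- split(edges$eid, edges$canon)[class_keys]

  cg <- list(k = k, comprehensive = g$comprehensive, genomes = g$genomes,
             contigs = g$contigs, oseq = g$oseq, frags = g$frags,
             vertices = vertices, rc_vid = rc_vid, jocc = jocc,
             edges = edges, o_eids = o_eids, o_cum = o_cum, o_frag = o_frag,
             in_map = in_map, class_keys = class_keys, class_eids = class_eids)
  class(cg) <- "cdbg"
  cg
}

#' @export
print.cdbg <- function(x, ...) {
  cat(sprintf("compacted de Bruijn graph: k=%d, %d junction k-mer(s), %d compacted edge(s), %d class(es)%s\n",
              x$k, length(x$vertices), nrow(x$edges), length(x$class_keys),
              if (x$comprehensive) ", double-stranded" else ""))
  invisible(x)
}

#' Reconstruct the input sequences from a compacted graph
#'
#' Concatenates the spelled sequences of the consecutive compacted edges
#' of every fragment (consecutive edges overlap by k characters).
#'
#' @param cg a `cdbg`.
#' @return list with one character vector per oriented sequence, holding
#'   the reconstructed fragment strings in order.
#' @export
decompress_graph <- function(cg) {
  out <- lapply(seq_len(nrow(cg$oseq)), function(o) {
    ids <- cg$o_eids[[as.character(o)]]
    sp <- if (is.null(ids)) list() else split(ids, cg$o_frag[[as.character(o)]])
    frag_strings <- vapply(sp, function(fe) {
      pieces <- cg$edges$spelled[fe]
      paste0(pieces[1L], paste(substring(pieces[-1L], cg$k + 1L), collapse = ""))
    }, character(1))
    # fragments of length exactly k have one junction occurrence and no edge
    jo <- cg$jocc[cg$jocc$oseq == o, , drop = FALSE]
    lonely <- setdiff(unique(jo$frag), as.integer(names(sp)))
    if (length(lonely)) {
      frag_strings <- c(frag_strings, vapply(lonely, function(f)
        jo$kmer[jo$frag == f][1L], character(1)))
    }
    unname(frag_strings)
  })
  names(out) <- paste(cg$contigs$genome_id[cg$oseq$contig_idx],
                      cg$contigs$seq_id[cg$oseq$contig_idx],
                      cg$oseq$strand, sep = ".")
  out
}

#' Dump a compacted graph as GFA1 (for inspection)
#'
#' Segments are the distinct spelled junction-to-junction sequences,
#' links are the adjacencies observed in the input (overlap k).
#'
#' @param cg a `cdbg`.
#' @param path output file.
#' @export
write_gfa <- function(cg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  keys <- cg$class_keys
  seg_id <- stats::setNames(seq_along(keys), keys)
  first <- !duplicated(cg$edges$canon)
  for (r in which(first)) {
    writeLines(sprintf("S\t%d\t%s", seg_id[[cg$edges$canon[r]]], cg$edges$spelled[r]), con)
  }
  links <- character(0)
  for (o in names(cg$o_eids)) {
    ids <- cg$o_eids[[o]]
    fr <- cg$o_frag[[o]]
    if (length(ids) < 2L) next
    a <- ids[-length(ids)]; b <- ids[-1L]
    okp <- fr[-length(fr)] == fr[-1L]
    la <- sprintf("L\t%d\t%s\t%d\t%s\t%dM",
                  seg_id[cg$edges$canon[a[okp]]],
                  ifelse(cg$edges$dir[a[okp]], "+", "-"),
                  seg_id[cg$edges$canon[b[okp]]],
                  ifelse(cg$edges$dir[b[okp]], "+", "-"), cg$k)
    links <- c(links, la)
  }
  writeLines(unique(links), con)
  invisible(path)
}

# --- small accessors used by the finder and the public walk API ---------

# Oriented-sequence label -> contig/strand description
oseq_desc <- function(cg, o) {
  ci <- cg$oseq$contig_idx[o]
  list(genome_id = cg$contigs$genome_id[ci], seq_id = cg$contigs$seq_id[ci],
       strand = cg$oseq$strand[o], len = cg$contigs$length[ci])
}

# Genomic interval (forward strand, 0-based half-open) covered by the
# edge-index range [i1, i2] of oriented sequence o.
walk_interval <- function(cg, o, i1, i2) {
  ids <- cg$o_eids[[as.character(o)]]
  e1 <- ids[i1]; e2 <- ids[i2]
  a <- cg$edges$off[e1]
  bb <- cg$edges$off[e2] + cg$edges$len[e2] + cg$k
  d <- oseq_desc(cg, o)
  if (d$strand == "+") c(a, bb) else c(d$len - bb, d$len - a)
}
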