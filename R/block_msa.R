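# Centre-star multiple alignment of block rows.
#
# Blocks of closely related genomes are near-identical, so a simple
# deterministic aligner suffices: pairwise global alignments under unit
# edit costs (match 0, mismatch 1, indel 1), a centre chosen to maximise
# summed pairwise identity, and gap merging by "once a gap, always a
# gap". Pairwise alignments use a banded dynamic program whose band is
# doubled until optimality is guaranteed.

# Exact unit-cost global alignment of two strings.
align_pair <- function(a, b) .align_pair_cpp(a, b)

#' Centre-star multiple alignment of a set of sequences
#'
#' @param sequences character vector (>= 2 non-empty strings).
#' @return list with `text` (aligned rows, gaps as `-`, same order as
#'   the input), `columns`, and `center` (index of the centre sequence).
#' @export
#' @examples
#' align_block(c("ACGT", "ACT"))$text
align_block <- function(sequences) {
  n <- length(sequences)
  if (n < 2L) stop_param("need at least two sequences")
  if (any(!nzchar(sequences))) stop_param("empty sequence in block")
  # pairwise alignments; identity = matches / alignment length
  ident <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_pair(sequences[i], sequences[j])
      cols <- nchar(al$a)
      ident[i, j] <- ident[j, i] <- (cols - al$dist) / cols
    }
  }
  center <- which.max(rowSums(ident))
  others <- setdiff(seq_len(n), center)
  Lc <- nchar(sequences[center])

  # per-pair gap profiles relative to the centre: counts of gap columns
  # before centre position p (slots 1..Lc+1)
  pals <- lapply(others, function(j) align_pair(sequences[center], sequences[j]))
  profiles <- lapply(pals, function(al) {
    ca <- strsplit(al$a, "", fixed = TRUE)[[1]]
    slot <- cumsum(ca != "-")
    slot[ca == "-"] <- slot[ca == "-"] + 1L   # gap before centre char slot+1
    tabulate(slot[ca == "-"], nbins = Lc + 1L)
  })
  master <- if (length(profiles)) do.call(pmax, profiles) else integer(Lc + 1L)

  pad <- function(chars_by_slot, widths) {
    # left-justify characters in each inserted slot, pad right with '-'
    segs <- vapply(seq_along(widths), function(p) {
      s <- chars_by_slot[[p]]
      paste0(s, strrep("-", widths[p] - nchar(s)))
    }, character(1))
    segs
  }
  cc <- strsplit(sequences[center], "", fixed = TRUE)[[1]]
  rows <- character(n)
  # centre row
  ins <- strrep("-", master)
  center_cols <- c(rbind(ins[seq_len(Lc)], cc))
  rows[center] <- paste0(paste(center_cols, collapse = ""), ins[Lc + 1L])
  for (t in seq_along(others)) {
    al <- pals[[t]]
    ca <- strsplit(al$a, "", fixed = TRUE)[[1]]
    cb <- strsplit(al$b, "", fixed = TRUE)[[1]]
    slot <- cumsum(ca != "-")
    gap_slot <- slot + (ca == "-")
    chars_by_slot <- lapply(seq_len(Lc + 1L), function(p)
      paste(cb[ca == "-" & gap_slot == p], collapse = ""))
    ins_t <- pad(chars_by_slot, master)
    matched <- cb[ca != "-"]
    row_cols <- c(rbind(ins_t[seq_len(Lc)], matched))
    rows[others[t]] <- paste0(paste(row_cols, collapse = ""), ins_t[Lc + 1L])
  }
  list(text = rows, columns = Lc + sum(master), center = center)
}

#' Align every block of a result and produce MAF-ready rows
#'
#' Extracts each occurrence's genomic sequence (reverse-complemented for
#' `-` strand occurrences), aligns the rows of each block with
#' [align_block()], and returns aligned blocks in block-id order.
#'
#' @param blocks a [block_set()].
#' @param genomes the [genome_set()] the blocks refer to.
#' @return list of aligned blocks: each a list with `block_id`, `occ`
#'   (occurrence table with `src_size`), and `text` (aligned rows).
#' @export
align_all <- function(blocks, genomes) {
  if (nrow(blocks) == 0L) return(list())
  out <- lapply(sort(unique(blocks$block_id)), function(bi) {
    occ <- blocks[blocks$block_id == bi, , drop = FALSE]
    seqs <- vapply(seq_len(nrow(occ)), function(r) {
      contig <- get_contig(genomes, occ$genome_id[r], occ$seq_id[r])
      if (occ$end[r] > nchar(contig) || occ$start[r] < 0L) {
        stop_param("occurrence outside contig in block ", bi)
      }
      s <- substr(contig, occ$start[r] + 1L, occ$end[r])
      if (occ$strand[r] == "-") revcomp(s) else s
    }, character(1))
    al <- align_block(seqs)
    occ$src_size <- genomes$length[match(paste(occ$genome_id, occ$seq_id),
                                         paste(genomes$genome_id, genomes$seq_id))]
    occ$sequence <- NULL
    list(block_id = bi, occ = as.data.frame(occ)[, c("genome_id", "seq_id", "start",
                                                     "end", "strand", "src_size")],
         text = al$text)
  })
  out
}
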