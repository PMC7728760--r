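# Alignment evaluation over homologous position pairs.
#
# An alignment is viewed as an equivalence relation over genome
# positions: every alignment column contributes one pair per pair of
# rows with nucleotides at that column. Recall and precision compare
# the predicted relation A against a truth relation H:
# recall = 1 - |H \ A| / |H|, precision = 1 - |A \ H| / |A|.

pair_key <- function(ga, sa, pa, gb, sb, pb, flip) {
  ka <- paste(ga, sa, pa, sep = "\r")
  kb <- paste(gb, sb, pb, sep = "\r")
  swap <- kb < ka
  tmp <- ka[swap]; ka[swap] <- kb[swap]; kb[swap] <- tmp
  paste(ka, kb, ifelse(flip, "-", "+"), sep = "\n")
}

#' Build a homology relation from explicit position pairs
#'
#' Pairs are unordered and strand-annotated: `flip` records whether the
#' two positions lie on opposite strands of their homology. Positions
#' are 0-based forward-strand coordinates.
#'
#' @param ga,sa,pa genome, contig and position of the first endpoint.
#' @param gb,sb,pb second endpoint.
#' @param flip logical: opposite-strand pair?
#' @return object of class `homology_relation`.
#' @export
homology_relation <- function(ga, sa, pa, gb, sb, pb, flip = FALSE) {
  self <- ga == gb & sa == sb & pa == pb
  key <- unique(pair_key(ga, sa, pa, gb, sb, pb, rep_len(flip, length(ga)))[!self])
  out <- list(keys = key)
  class(out) <- "homology_relation"
  out
}

#' @export
print.homology_relation <- function(x, ...) {
  cat(sprintf("homology relation: %d position pair(s)\n", length(x$keys)))
  invisible(x)
}

#' @export
length.homology_relation <- function(x) length(x$keys)

#' Homologous position pairs induced by aligned blocks
#'
#' Every alignment column contributes one pair for each pair of rows
#' holding a nucleotide (gaps contribute nothing); positions are mapped
#' back to forward-strand coordinates, with the pair flagged as flipped
#' when the two rows lie on opposite strands.
#'
#' @param aligned_blocks list of aligned blocks ([align_all()] or
#'   [read_maf()]).
#' @return a [homology_relation()].
#' @export
relation_from_maf <- function(aligned_blocks) {
  acc <- vector("list", length(aligned_blocks))
  for (bi in seq_along(aligned_blocks)) {
    ab <- aligned_blocks[[bi]]
    nr <- length(ab$text)
    if (nr < 2L) next
    mat <- do.call(rbind, strsplit(ab$text, "", fixed = TRUE))
    nongap <- mat != "-"
    pos <- matrix(NA_integer_, nr, ncol(mat))
    for (r in seq_len(nr)) {
      j <- cumsum(nongap[r, ]) - 1L
      pos[r, nongap[r, ]] <- if (ab$occ$strand[r] == "+") {
        ab$occ$start[r] + j[nongap[r, ]]
      } else {
        ab$occ$end[r] - 1L - j[nongap[r, ]]
      }
    }
    prs <- list()
    for (r1 in seq_len(nr - 1L)) {
      for (r2 in (r1 + 1L):nr) {
        ok <- nongap[r1, ] & nongap[r2, ]
        if (!any(ok)) next
        prs[[length(prs) + 1L]] <- data.frame(
          ga = ab$occ$genome_id[r1], sa = ab$occ$seq_id[r1], pa = pos[r1, ok],
          gb = ab$occ$genome_id[r2], sb = ab$occ$seq_id[r2], pb = pos[r2, ok],
          flip = ab$occ$strand[r1] != ab$occ$strand[r2],
          stringsAsFactors = FALSE)
      }
    }
    if (length(prs)) acc[[bi]] <- do.call(rbind, prs)
  }
  d <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  if (is.null(d)) return(homology_relation(character(0), character(0), integer(0),
                                           character(0), character(0), integer(0)))
  homology_relation(d$ga, d$sa, d$pa, d$gb, d$sb, d$pb, d$flip)
}

#' Recall of an alignment against a truth relation
#'
#' @param truth truth relation H (non-empty).
#' @param pred predicted relation A.
#' @return `1 - |H \\ A| / |H|`.
#' @export
pair_recall <- function(truth, pred) {
  if (length(truth$keys) == 0L) stop_param("recall undefined: empty truth relation")
  mean(truth$keys %in% pred$keys)
}

#' Precision of an alignment against a truth relation
#'
#' @param truth truth relation H.
#' @param pred predicted relation A (non-empty).
#' @return `1 - |A \\ H| / |A|`.
#' @export
pair_precision <- function(truth, pred) {
  if (length(pred$keys) == 0L) stop_param("precision undefined: empty predicted relation")
  mean(pred$keys %in% truth$keys)
}

#' Fraction of the genomes covered by blocks
#'
#' @param blocks a [block_set()].
#' @param genomes the [genome_set()].
#' @return covered positions / total genome length.
#' @export
block_coverage <- function(blocks, genomes) {
  total <- sum(genomes$length)
  if (nrow(blocks) == 0L) return(0)
  covered <- 0
  for (ct in unique(paste(blocks$genome_id, blocks$seq_id))) {
    sel <- paste(blocks$genome_id, blocks$seq_id) == ct
    ir <- IRanges::reduce(IRanges::IRanges(start = blocks$start[sel] + 1L,
                                           end = blocks$end[sel]))
    covered <- covered + sum(IRanges::width(ir))
  }
  covered / total
}

#' Average number of pairwise nucleotide differences in one column
#'
#' `pi(c) = sum_{i<j} I(c_i != c_j) / C(|c|, 2)` where the indicator is
#' 1 only when both characters are distinct valid DNA characters
#' (A/C/G/T); gaps and ambiguity codes contribute 0 but still count in
#' the denominator.
#'
#' @param column character vector of column entries (length >= 2).
#' @return numeric in [0, 1].
#' @export
pi_column <- function(column) {
  n <- length(column)
  if (n < 2L) stop_param("pi undefined for a column with fewer than 2 rows")
  valid <- column %in% c("A", "C", "G", "T")
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    cnt <- cnt + sum(valid[i] & valid[(i + 1L):n] & column[i] != column[(i + 1L):n])
  }
  cnt / choose(n, 2)
}

#' Per-column pi values of aligned blocks
#'
#' @param aligned_blocks list of aligned blocks (>= 2 rows each).
#' @return numeric vector, one value per alignment column over all blocks.
#' @export
pi_columns <- function(aligned_blocks) {
  unlist(lapply(aligned_blocks, function(ab) {
    mat <- do.call(rbind, strsplit(ab$text, "", fixed = TRUE))
    nr <- nrow(mat)
    if (nr < 2L) return(numeric(0))
    valid <- mat %in% c("A", "C", "G", "T")
    dim(valid) <- dim(mat)
    cnt <- numeric(ncol(mat))
    for (i in seq_len(nr - 1L)) {
      for (j in (i + 1L):nr) {
        cnt <- cnt + (valid[i, ] & valid[j, ] & mat[i, ] != mat[j, ])
      }
    }
    cnt / choose(nr, 2)
  }))
}

#' Nucleotide identity of two aligned rows
#'
#' Matched nucleotides divided by the alignment length including gap
#' columns.
#'
#' @param a,b equal-length aligned strings.
#' @return numeric in [0, 1].
#' @export
nucleotide_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop_param("aligned rows have different lengths")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' Bin identities into left-closed bins
#'
#' @param values identities in [0, 1].
#' @param width bin width (default 0.05).
#' @return table of counts per bin.
#' @export
identity_bins <- function(values, width = 0.05) {
  brk <- round(seq(0, 1, by = width), 10)   # exact decimal bin edges
  table(cut(values, breaks = unique(c(brk, 1)), right = FALSE, include.lowest = TRUE))
}

#' Evaluate a predicted alignment against a truth relation
#'
#' @param pred aligned blocks, or a [homology_relation()], or a MAF path.
#' @param truth a [homology_relation()], a truth TSV path (from
#'   [write_truth_tsv()]), or a MAF path.
#' @return list with `recall`, `precision`, `n_pred`, `n_truth`.
#' @export
evaluate_alignment <- function(pred, truth) {
  as_rel <- function(x) {
    if (inherits(x, "homology_relation")) return(x)
    if (is.character(x) && length(x) == 1L) {
      first <- readLines(x, n = 1L)
      if (startsWith(first, "##maf")) return(relation_from_maf(read_maf(x)))
      return(read_truth_tsv(x))
    }
    relation_from_maf(x)
  }
  A <- as_rel(pred); H <- as_rel(truth)
  list(recall = pair_recall(H, A), precision = pair_precision(H, A),
       n_pred = length(A$keys), n_truth = length(H$keys))
}
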