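# Reading genomes and writing blocks/alignments in standard formats.
#
# Internal coordinates are 0-based, half-open, on the forward strand;
# conversions to the 1-based (GFF) and strand-relative (MAF) conventions
# happen only in the writers/readers below.

#' Construct a genome set from in-memory sequences
#'
#' A genome set is the package's container for a collection of assembled
#' genomes: one row per contig with its genome label, contig identifier
#' and (uppercased) sequence.
#'
#' @param sequences character vector of contig sequences.
#' @param genome_id single genome label, or one per contig.
#' @param seq_id contig identifiers (defaults to `names(sequences)` or
#'   `seq1`, `seq2`, ...).
#' @return an object of class `genome_set`: a data.frame with columns
#'   `genome_id`, `seq_id`, `sequence`, `length`.
#' @export
#' @examples
#' gs <- genome_set(c(g1 = "GCACGTCC", g2 = "GCACTTCC"), genome_id = c("g1", "g2"))
genome_set <- function(sequences, genome_id = "genome", seq_id = NULL) {
  if (length(sequences) == 0L) stop_param("empty input: no sequences")
  if (is.null(seq_id)) {
    seq_id <- names(sequences) %||% paste0("seq", seq_along(sequences))
    if (is.null(names(sequences))) seq_id <- paste0("seq", seq_along(sequences))
  }
  genome_id <- rep_len(as.character(genome_id), length(sequences))
  sequences <- toupper(as.character(sequences))
  bad <- !grepl(paste0("^[", paste(IUPAC_CHARS, collapse = ""), "]*$"), sequences)
  if (any(bad)) {
    stop_param("sequence ", seq_id[which(bad)[1]], " contains non-IUPAC characters")
  }
  if (any(nchar(sequences) == 0L)) {
    stop_param("empty contig ", seq_id[which(nchar(sequences) == 0L)[1]])
  }
  key <- paste(genome_id, seq_id)
  if (anyDuplicated(key)) stop_param("duplicated (genome_id, seq_id): ", key[duplicated(key)][1])
  out <- data.frame(genome_id = genome_id, seq_id = as.character(seq_id),
                    sequence = sequences, length = nchar(sequences),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_set", "data.frame")
  out
}

#' Read one genome from a FASTA file
#'
#' Each contig becomes one record, in file order. Lowercase is normalised
#' to uppercase; characters outside the IUPAC alphabet are rejected with
#' the offending line number.
#'
#' @param path FASTA file.
#' @param genome_id label shared by all contigs of this file.
#' @return a [genome_set()].
#' @export
read_fasta <- function(path, genome_id = sub("\\.(fa|fasta|fna)$", "", basename(path))) {
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines))) stop_param("empty input: ", path)
  first <- which(nzchar(lines))[1]
  if (!startsWith(lines[first], ">")) {
    stop_param("malformed FASTA at line ", first, ": expected '>' header")
  }
  alpha <- paste0("^[", paste(IUPAC_CHARS, collapse = ""), "]*$")
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, ">")) next
    if (!grepl(alpha, toupper(ln))) {
      stop_param("malformed FASTA at line ", i, ": non-IUPAC characters")
    }
  }
  ss <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(ss) == 0L)) {
    stop_param("empty contig ", names(ss)[Biostrings::width(ss) == 0L][1])
  }
  ids <- sub("\\s.*$", "", names(ss))
  genome_set(as.character(ss), genome_id = genome_id, seq_id = ids)
}

#' Read several genomes, one FASTA file each
#'
#' @param paths character vector of FASTA files.
#' @param genome_ids labels, one per file (defaults to file base names).
#' @return a combined [genome_set()].
#' @export
read_genomes <- function(paths, genome_ids = sub("\\.(fa|fasta|fna)$", "", basename(paths))) {
  parts <- Map(read_fasta, paths, genome_ids)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("genome_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write a genome set to FASTA
#'
#' One file per call; headers are `genome_id.seq_id` unless the set holds
#' a single genome, in which case plain `seq_id` is used.
#'
#' @param genomes a [genome_set()].
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  nm <- if (length(unique(genomes$genome_id)) > 1L) {
    paste(genomes$genome_id, genomes$seq_id, sep = ".")
  } else genomes$seq_id
  ss <- Biostrings::BStringSet(genomes$sequence)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# Fetch one contig sequence (forward strand).
get_contig <- function(genomes, genome_id, seq_id) {
  i <- which(genomes$genome_id == genome_id & genomes$seq_id == seq_id)
  if (length(i) != 1L) stop_param("unknown contig ", genome_id, ".", seq_id)
  genomes$sequence[i]
}

## ---------------------------------------------------------------------------
## Block records

#' Assemble a block record table
#'
#' A block is a set of at least two occurrences, each a 0-based half-open
#' interval on the forward strand of a contig with a strand label.
#' Occurrences of all blocks are pairwise non-overlapping.
#'
#' @param block_id integer block ids, one per occurrence.
#' @param genome_id,seq_id,start,end,strand occurrence fields.
#' @return an object of class `block_set` (a data.frame).
#' @export
block_set <- function(block_id, genome_id, seq_id, start, end, strand) {
  out <- data.frame(block_id = as.integer(block_id), genome_id = as.character(genome_id),
                    seq_id = as.character(seq_id), start = as.integer(start),
                    end = as.integer(end), strand = as.character(strand),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop_param("empty occurrence interval")
  if (!all(out$strand %in% c("+", "-"))) stop_param("strand must be + or -")
  out <- out[order(out$block_id, out$genome_id, out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("block_set", "data.frame")
  out
}

#' Write block coordinates as GFF3
#'
#' One feature per occurrence, 1-based inclusive coordinates, with the
#' block id in the `ID` attribute (`ID=block_<n>`) and the genome label in
#' a `genome` attribute. Features are ordered by (block, genome, contig,
#' start).
#'
#' @param blocks a [block_set()].
#' @param path output file.
#' @export
write_blocks_gff <- function(blocks, path) {
  if (nrow(blocks) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = paste(blocks$genome_id, blocks$seq_id, sep = "."),
    ranges = IRanges::IRanges(start = blocks$start + 1L, end = blocks$end),
    strand = blocks$strand)
  S4Vectors::mcols(gr)$source <- "lcblocks"
  S4Vectors::mcols(gr)$type <- "match"
  S4Vectors::mcols(gr)$ID <- paste0("block_", blocks$block_id)
  S4Vectors::mcols(gr)$genome <- blocks$genome_id
  S4Vectors::mcols(gr)$contig <- blocks$seq_id
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read block coordinates back from GFF3
#'
#' Inverse of [write_blocks_gff()]: returns 0-based half-open intervals.
#'
#' @param path GFF3 file written by [write_blocks_gff()].
#' @return a [block_set()].
#' @export
read_blocks_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  if (length(gr) == 0L) {
    out <- data.frame(block_id = integer(0), genome_id = character(0),
                      seq_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    class(out) <- c("block_set", "data.frame")
    return(out)
  }
  block_set(block_id = as.integer(sub("^block_", "", S4Vectors::mcols(gr)$ID)),
            genome_id = S4Vectors::mcols(gr)$genome,
            seq_id = S4Vectors::mcols(gr)$contig,
            start = BiocGenerics::start(gr) - 1L,
            end = BiocGenerics::end(gr),
            strand = as.character(BiocGenerics::strand(gr)))
}

## ---------------------------------------------------------------------------
## MAF (multiple alignment format)
##
## No installed R package reads or writes MAF, so a minimal writer/parser
## for the "a"/"s" paragraph structure lives here.

#' Write aligned blocks as MAF
#'
#' One `a` paragraph per block and one `s` line per row. Rows on the
#' reverse strand follow the MAF convention: `start` counts from the
#' beginning of the reverse-complemented source and the text is the
#' reverse-complement of the forward interval.
#'
#' @param aligned_blocks list of aligned blocks from [align_all()].
#' @param path output file.
#' @export
write_maf <- function(aligned_blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (ab in aligned_blocks) {
    if (length(unique(nchar(ab$text))) > 1L) {
      stop_param("ragged alignment rows in block ", ab$block_id)
    }
    writeLines("", con)
    writeLines(paste0("a label=block_", ab$block_id), con)
    occ <- ab$occ
    src <- paste(occ$genome_id, occ$seq_id, sep = ".")
    size <- occ$end - occ$start
    start <- ifelse(occ$strand == "+", occ$start, occ$src_size - occ$end)
    writeLines(sprintf("s %s %d %d %s %d %s", src, start, size, occ$strand,
                       occ$src_size, ab$text), con)
  }
  invisible(path)
}

#' Read a MAF file written by [write_maf()]
#'
#' @param path MAF file.
#' @return list of aligned blocks (same shape as [align_all()] output).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  bid <- 0L
  flush <- function(cur) {
    if (is.null(cur) || length(cur$text) == 0L) return(NULL)
    if (length(unique(nchar(cur$text))) > 1L) stop_param("ragged MAF block")
    cur
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      bid <- bid + 1L
      lab <- regmatches(ln, regexpr("label=block_[0-9]+", ln))
      id <- if (length(lab)) as.integer(sub("label=block_", "", lab)) else bid
      cur <- list(block_id = id,
                  occ = data.frame(genome_id = character(0), seq_id = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0), src_size = integer(0),
                                   stringsAsFactors = FALSE),
                  text = character(0))
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      src <- f[2]; start <- as.integer(f[3]); size <- as.integer(f[4])
      strand <- f[5]; src_size <- as.integer(f[6]); text <- f[7]
      dot <- regexpr(".", src, fixed = TRUE)
      gid <- substr(src, 1L, dot - 1L)
      sid <- substr(src, dot + 1L, nchar(src))
      fs <- if (strand == "+") start else src_size - start - size
      cur$occ <- rbind(cur$occ, data.frame(genome_id = gid, seq_id = sid,
                                           start = fs, end = fs + size,
                                           strand = strand, src_size = src_size,
                                           stringsAsFactors = FALSE))
      cur$text <- c(cur$text, text)
    }
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}
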