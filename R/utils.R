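# Internal helpers shared across modules.

.datatable.aware <- TRUE

# IUPAC nucleotide codes accepted on ingest (gap codes excluded).
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised over the input; IUPAC ambiguity codes are complemented
#' according to their standard pairing.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("GCACGTCC")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorised k-mer extraction: all substrings of length `len` of `seq`
# starting at 0-based offsets `offs`.
substr_at <- function(seq, offs, len) {
  substring(seq, offs + 1L, offs + len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
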