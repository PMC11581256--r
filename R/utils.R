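# Internal helpers shared across modules.


#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse a plain character string (used for quality strings).
str_rev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Phred+33 encoding helpers.
qual_to_int <- function(q) {
  if (nchar(q) == 0L) return(integer(0))
  utf8ToInt(q) - 33L
}

int_to_qual <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(q + 33L)
}

# Split a vector of sequences into a list of character vectors (one char per base).
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Empty read set with the canonical columns.
empty_reads <- function() {
  data.frame(id = character(0), seq = character(0), qual = character(0),
             stringsAsFactors = FALSE)
}

# Validate a read-set data frame (id/seq/qual columns, matching lengths).
check_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) > 0L && any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence and quality lengths differ")
  invisible(reads)
}

# Empty alignment table with the canonical columns.
empty_alignments <- function() {
  data.frame(read_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), seq = character(0), qual = character(0),
             score = integer(0), mapq = integer(0), n_mismatch = integer(0),
             end_mode = character(0), stringsAsFactors = FALSE)
}

check_alignments <- function(aln) {
  stopifnot(is.data.frame(aln),
            all(c("read_id", "start", "end", "strand", "seq", "qual", "mapq") %in% names(aln)))
  if (!"end_mode" %in% names(aln)) aln$end_mode <- rep("both", nrow(aln))
  aln
}
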