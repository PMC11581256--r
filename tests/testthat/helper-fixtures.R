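# Shared fixtures, built once per test run. All references are synthetic
# seeded sequences; nothing is read from disk.

.fixtures <- new.env()

fix <- function() {
  if (is.null(.fixtures$ref)) {
    .fixtures$ref <- synthetic_circular_reference(seed = 101L)
    .fixtures$lin <- linearize_reference(.fixtures$ref)
    .fixtures$panel <- default_panel(.fixtures$lin)
    .fixtures$index <- build_index(.fixtures$lin)
  }
  .fixtures
}

# Build a read-set data frame from sequences with a constant quality.
mk_reads <- function(seqs, q = 30L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(id = ids, seq = seqs,
             qual = strrep(intToUtf8(q + 33L), nchar(seqs)),
             stringsAsFactors = FALSE)
}

# A variant token at circular position `pos` guaranteed to differ from `ref`.
alt_token <- function(ref, pos) {
  b <- substring(ref$sequence, pos, pos)
  paste0(pos, setdiff(c("A", "C", "G", "T"), b)[1L])
}

# Minimal alignment row(s) for unit tests.
mk_aln <- function(start, end, strand = "+", seq = NULL, q = 30L,
                   mapq = 60L, end_mode = "both", lin = NULL, ids = NULL) {
  n <- length(start)
  if (is.null(seq)) {
    stopifnot(!is.null(lin))
    seq <- substring(lin$sequence, start, end)
    neg <- strand == "-"
    if (any(neg)) seq[neg] <- mtamplicon_revcomp(seq[neg])
  }
  if (is.null(ids)) ids <- sprintf("a%04d", seq_len(n))
  data.frame(read_id = ids, start = start, end = end,
             strand = rep_len(strand, n), seq = seq,
             qual = strrep(intToUtf8(q + 33L), nchar(seq)),
             score = nchar(seq), mapq = rep_len(mapq, n),
             n_mismatch = 0L, end_mode = rep_len(end_mode, n),
             stringsAsFactors = FALSE)
}

# Reverse complement without reaching into package internals.
mtamplicon_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Circular positions of variant tokens like "16126C".
parse_token_pos <- function(tokens) as.integer(sub("[A-Z]$", "", tokens))

# Pre-damage reference base at molecule-orientation position `at` for every molecule
# (vectorized: "+" reads the window left-to-right, "-" the complement right-to-left).
oriented_ref_base <- function(lin, mols, at) {
  pos_fwd <- ifelse(mols$strand == "+", mols$lin_start + at - 1L,
                    mols$lin_end - at + 1L)
  b <- substring(lin$sequence, pos_fwd, pos_fwd)
  neg <- mols$strand == "-"
  b[neg] <- chartr("ACGT", "TGCA", b[neg])
  b
}
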