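# Seed-and-extend ungapped alignment to the linearized NCR, with SAM interchange.
#
# At NCR scale (~1.4 kb) a k-mer hash plus ungapped extension places reads exactly;
# the downstream variant caller ignores indels, so gapped alignment adds nothing here.
# The mapping quality is a simple gap-to-second-best proxy, chosen so the pipeline's
# strict "mapping quality over 30" filter is meaningful: a read with no competing
# placement saturates at 60, tied placements get 0.

#' Build a k-mer index of a linearized reference
#'
#' Indexes every k-mer start position on both strands (reverse-strand k-mers are the
#' k-mers of the reverse complement, recorded at their forward-strand start position).
#'
#' @param lin A `linearized_ncr`.
#' @param k K-mer length (default 13; at least 8 to limit spurious seeds).
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(lin, k = 13L) {
  stopifnot(inherits(lin, "linearized_ncr"))
  k <- as.integer(k)
  if (k < 8L) stop("k below 8 risks spurious seeds")
  if (k > lin$length) stop("k exceeds the reference length")
  L <- lin$length
  starts <- seq_len(L - k + 1L)
  fwd_kmers <- substring(lin$sequence, starts, starts + k - 1L)
  rc_seq <- revcomp(lin$sequence)
  rc_kmers <- substring(rc_seq, starts, starts + k - 1L)
  # a reverse-strand k-mer starting at position i of the reverse complement covers
  # forward positions (L - k - i + 2) .. (L - i + 1)
  rev_starts <- L - k - starts + 2L
  structure(list(k = k,
                 fwd = split(starts, fwd_kmers),
                 rev = split(rev_starts, rc_kmers),
                 ref_chars = strsplit(lin$sequence, "", fixed = TRUE)[[1L]],
                 ref_id = lin$id, length = L),
            class = "kmer_index")
}

#' Look up a k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer K-mer string of length `index$k`.
#' @return List with sorted forward- and reverse-strand start positions.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"), nchar(kmer) == index$k)
  list(fwd = sort(as.integer(index$fwd[[kmer]])),
       rev = sort(as.integer(index$rev[[kmer]])))
}

# Candidate start positions for an oriented read via seed lookups at a stride.
seed_candidates <- function(index, seq, len) {
  k <- index$k
  if (len < k) return(integer(0))
  offs <- unique(c(seq(1L, len - k + 1L, by = 5L), len - k + 1L))
  cand <- integer(0)
  for (o in offs) {
    hits <- index$fwd[[substr(seq, o, o + k - 1L)]]
    if (!is.null(hits)) cand <- c(cand, hits - o + 1L)
  }
  unique(cand)
}

#' Align reads to the indexed reference
#'
#' Seed-and-extend, ungapped, scoring +1 per match and -1 per mismatch. The best
#' placement is reported when its score reaches `min_score_fraction` of the read
#' length; mapping quality is `min(60, 4 * (best - second_best))`, with `second_best`
#' taken as 0 for a unique placement (ties therefore map to 0).
#'
#' @param index A `kmer_index`.
#' @param reads Read-set data frame; reads shorter than 30 bp are rejected.
#' @param min_score_fraction Minimum best score as a fraction of read length.
#' @param end_mode Damage-geometry tag attached to every produced alignment: `"both"`
#'   for reads whose two ends are genuine molecule ends (merged reads), `"five"`/
#'   `"three"` for unmerged mates that only carry the molecule's 5'/3' end.
#' @return An alignment data frame with one row per mapped read: `read_id`, `start`,
#'   `end` (1-based closed, linear), `strand`, `seq`/`qual` (sequenced orientation),
#'   `score`, `mapq`, `n_mismatch`, `end_mode`. Unmapped reads are omitted; their ids
#'   are in attribute `"unmapped"`.
#' @export
align_reads <- function(index, reads, min_score_fraction = 0.8, end_mode = "both") {
  stopifnot(inherits(index, "kmer_index"))
  check_reads(reads)
  n <- nrow(reads)
  if (n == 0L) {
    out <- empty_alignments()
    attr(out, "unmapped") <- character(0)
    return(out)
  }
  if (any(nchar(reads$seq) < 30L)) stop("reads shorter than 30 bp cannot be aligned")
  refc <- index$ref_chars
  L <- index$length
  res_start <- integer(n); res_strand <- character(n)
  res_score <- integer(n); res_mapq <- integer(n); res_mm <- integer(n)
  mapped <- logical(n)
  rc_seqs <- revcomp(reads$seq)
  for (i in seq_len(n)) {
    len <- nchar(reads$seq[i])
    best <- -Inf; second <- -Inf
    best_start <- NA_integer_; best_strand <- NA_character_; best_mm <- NA_integer_
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") reads$seq[i] else rc_seqs[i]
      oc <- strsplit(oriented, "", fixed = TRUE)[[1L]]
      for (s in seed_candidates(index, oriented, len)) {
        if (s < 1L || s + len - 1L > L) next
        matches <- sum(refc[s:(s + len - 1L)] == oc)
        sc <- 2L * matches - len
        if (sc > best) {
          second <- best
          best <- sc; best_start <- s; best_strand <- strand
          best_mm <- len - matches
        } else if (sc > second) {
          second <- sc
        }
      }
    }
    if (is.finite(best) && best >= min_score_fraction * len) {
      mapped[i] <- TRUE
      res_start[i] <- best_start
      res_strand[i] <- best_strand
      res_score[i] <- best
      res_mm[i] <- best_mm
      gap <- if (is.finite(second)) best - second else best
      res_mapq[i] <- max(0L, min(60L, as.integer(4L * gap)))
    }
  }
  out <- data.frame(read_id = reads$id[mapped],
                    start = res_start[mapped],
                    end = res_start[mapped] + nchar(reads$seq[mapped]) - 1L,
                    strand = res_strand[mapped],
                    seq = reads$seq[mapped], qual = reads$qual[mapped],
                    score = res_score[mapped], mapq = res_mapq[mapped],
                    n_mismatch = res_mm[mapped],
                    end_mode = rep(end_mode, sum(mapped)),
                    stringsAsFactors = FALSE)
  attr(out, "unmapped") <- reads$id[!mapped]
  out
}

#' Filter alignments by mapping quality
#'
#' Keeps alignments with mapping quality strictly over `min_mapq` (default 30); the
#' survivors are the sample's "useful reads".
#'
#' @param aln Alignment data frame.
#' @param min_mapq Strict lower bound on mapping quality.
#' @return The filtered alignment data frame.
#' @export
mapq_filter <- function(aln, min_mapq = 30L) {
  aln <- check_alignments(aln)
  out <- aln[aln$mapq > min_mapq, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write alignments as SAM
#'
#' Standard uncompressed SAM with the linearized reference as the single sequence.
#' Reverse-strand records store the reverse-complemented sequence and reversed
#' qualities with FLAG 16, per SAM convention. `NM` carries the mismatch count, `AS`
#' the alignment score, and `XE` the end-mode tag so a round trip is lossless.
#'
#' @param aln Alignment data frame.
#' @param lin The `linearized_ncr` the alignments refer to.
#' @param path Output path.
#' @export
emit_sam <- function(aln, lin, path) {
  aln <- check_alignments(aln)
  stopifnot(inherits(lin, "linearized_ncr"))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", lin$id, "\tLN:", lin$length))
  if (nrow(aln) > 0L) {
    neg <- aln$strand == "-"
    seq_out <- aln$seq; qual_out <- aln$qual
    seq_out[neg] <- revcomp(aln$seq[neg])
    qual_out[neg] <- str_rev(aln$qual[neg])
    body <- paste(aln$read_id,
                  ifelse(neg, 16L, 0L),
                  lin$id,
                  aln$start,
                  aln$mapq,
                  paste0(nchar(aln$seq), "M"),
                  "*", 0L, 0L,
                  seq_out, qual_out,
                  paste0("NM:i:", ifelse(is.na(aln$n_mismatch), 0L, aln$n_mismatch)),
                  paste0("AS:i:", ifelse(is.na(aln$score), 0L, aln$score)),
                  paste0("XE:Z:", aln$end_mode),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load alignments from a SAM file
#'
#' Accepts the single-reference ungapped SAM produced by [emit_sam()] (or equivalent
#' external files); records mapped to an unknown reference name are rejected, unmapped
#' records (FLAG 0x4) are skipped.
#'
#' @param path SAM path.
#' @param lin The `linearized_ncr` the file must refer to.
#' @return An alignment data frame (sequences restored to sequenced orientation).
#' @export
load_sam <- function(path, lin) {
  stopifnot(inherits(lin, "linearized_ncr"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 11L)) stop("malformed SAM record(s)")
  flag <- as.integer(vapply(fields, `[`, character(1), 2L))
  keep <- bitwAnd(flag, 4L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  if (length(fields) == 0L) return(empty_alignments())
  rname <- vapply(fields, `[`, character(1), 3L)
  if (any(rname != lin$id))
    stop("SAM reference name(s) do not match the linearized reference: ",
         paste(unique(rname[rname != lin$id]), collapse = ", "))
  get_tag <- function(f, tag, default) {
    if (length(f) < 12L) return(default)
    hit <- grep(paste0("^", tag, ":"), f[12:length(f)], value = TRUE)
    if (length(hit) == 0L) default else sub(paste0("^", tag, ":[AifZ]:"), "", hit[1L])
  }
  neg <- bitwAnd(flag, 16L) != 0L
  seqs <- vapply(fields, `[`, character(1), 10L)
  quals <- vapply(fields, `[`, character(1), 11L)
  seqs[neg] <- revcomp(seqs[neg])
  quals[neg] <- str_rev(quals[neg])
  start <- as.integer(vapply(fields, `[`, character(1), 4L))
  data.frame(read_id = vapply(fields, `[`, character(1), 1L),
             start = start,
             end = start + nchar(seqs) - 1L,
             strand = ifelse(neg, "-", "+"),
             seq = seqs, qual = quals,
             score = as.integer(vapply(fields, get_tag, character(1), "AS", "0")),
             mapq = as.integer(vapply(fields, `[`, character(1), 5L)),
             n_mismatch = as.integer(vapply(fields, get_tag, character(1), "NM", "0")),
             end_mode = vapply(fields, get_tag, character(1), "XE", "both"),
             stringsAsFactors = FALSE)
}
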