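# Read preprocessing and the two duplicate-removal engines.
#
# Trimming is one composite pass applying, in order: 3' adapter removal, poly-X tail
# removal, fixed primer trims (primers are unpublished, so fixed 25/5 bp end trims are
# used), 3' quality trimming, and a minimum-length filter. Deduplication comes in the
# two flavours compared for amplicon data: exact-sequence identity (appropriate for
# amplicons, where distinct template molecules share coordinates) and coordinate-class
# identity (the convention of coordinate-based tools, which collapses an amplicon's
# distinct molecules into one read).

DEFAULT_ADAPTERS <- c(TRUSEQ_ADAPTER_R1, TRUSEQ_ADAPTER_R2)

# Find the earliest read position where the adapter prefix matches the read suffix,
# allowing 1 mismatch per 8 matched bases; 0 if no adapter found. Minimum match 4 bases.
find_adapter_start <- function(chars, adapter_chars, min_match = 4L) {
  n <- length(chars)
  na <- length(adapter_chars)
  cand <- which(chars == adapter_chars[1L])
  cand <- cand[cand <= n - min_match + 1L]
  for (j in cand) {
    ov <- min(n - j + 1L, na)
    mism <- sum(chars[j:(j + ov - 1L)] != adapter_chars[seq_len(ov)])
    if (mism <= ov %/% 8L) return(j)
  }
  0L
}

# Length of the trailing single-base run.
polyx_run_length <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(0L)
  last <- chars[n]
  i <- n
  while (i > 1L && chars[i - 1L] == last) i <- i - 1L
  n - i + 1L
}

#' Trim reads (adapter, poly-X, primer, quality, length filter)
#'
#' Applies, in order: 3' adapter removal (suffix match against each adapter prefix,
#' allowing 1 mismatch per 8 matched bases), poly-X tail removal (trailing single-base
#' run of at least `polyx_min_run`), fixed primer trims (`primer_trim_5p` bases from the
#' 5' end, `primer_trim_3p` from the 3' end), removal of trailing bases with quality
#' below `min_qual_3p`, and a minimum-length filter.
#'
#' @param reads Read-set data frame (`id`, `seq`, `qual`).
#' @param adapters Character vector of 3' adapter sequences.
#' @param primer_trim_5p,primer_trim_3p Fixed primer-trim lengths (bp).
#' @param min_qual_3p Phred threshold for 3' quality trimming.
#' @param min_length Reads shorter than this after all trims are dropped.
#' @param polyx_min_run Minimum trailing homopolymer run length for poly-X removal.
#' @return A read-set data frame of surviving reads, with attribute `"dropped"` holding
#'   the ids of reads removed by the length filter.
#' @export
trim_reads <- function(reads, adapters = DEFAULT_ADAPTERS,
                       primer_trim_5p = 25L, primer_trim_3p = 5L,
                       min_qual_3p = 20L, min_length = 30L, polyx_min_run = 10L) {
  check_reads(reads)
  n <- nrow(reads)
  if (n == 0L) {
    out <- empty_reads()
    attr(out, "dropped") <- character(0)
    return(out)
  }
  adapter_chars <- seq_chars(toupper(adapters))
  all_chars <- seq_chars(reads$seq)
  out_seq <- character(n); out_qual <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    chars <- all_chars[[i]]
    quals <- qual_to_int(reads$qual[i])
    # 1. adapter removal: earliest hit over all adapters
    hit <- 0L
    for (ac in adapter_chars) {
      h <- find_adapter_start(chars, ac)
      if (h > 0L && (hit == 0L || h < hit)) hit <- h
    }
    if (hit > 0L) {
      chars <- chars[seq_len(hit - 1L)]
      quals <- quals[seq_len(hit - 1L)]
    }
    # 2. poly-X tail
    run <- polyx_run_length(chars)
    if (run >= polyx_min_run) {
      keep_n <- length(chars) - run
      chars <- chars[seq_len(keep_n)]
      quals <- quals[seq_len(keep_n)]
    }
    # 3. fixed primer trims
    len <- length(chars)
    if (len > primer_trim_5p + primer_trim_3p) {
      sel <- (primer_trim_5p + 1L):(len - primer_trim_3p)
      chars <- chars[sel]; quals <- quals[sel]
    } else {
      chars <- character(0); quals <- integer(0)
    }
    # 4. 3' quality trim
    len <- length(chars)
    while (len > 0L && quals[len] < min_qual_3p) len <- len - 1L
    chars <- chars[seq_len(len)]; quals <- quals[seq_len(len)]
    # 5. length filter
    if (length(chars) >= min_length) {
      keep[i] <- TRUE
      out_seq[i] <- paste(chars, collapse = "")
      out_qual[i] <- int_to_qual(quals)
    }
  }
  out <- data.frame(id = reads$id[keep], seq = out_seq[keep], qual = out_qual[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- reads$id[!keep]
  out
}

# Evaluate one overlap offset; returns mismatches and overlap length.
overlap_stats <- function(c1, c2, off) {
  # c2 is placed so its first base sits at position off+1 of c1's frame.
  a <- max(1L, off + 1L)
  b <- min(length(c1), off + length(c2))
  if (b < a) return(c(mism = NA_integer_, ov = 0L))
  i1 <- a:b
  i2 <- (a - off):(b - off)
  c(mism = sum(c1[i1] != c2[i2]), ov = b - a + 1L)
}

# Merge one pair given a valid offset (vectorized over merged positions).
merge_at_offset <- function(c1, q1, c2, q2, off) {
  lo <- min(1L, off + 1L)
  hi <- max(length(c1), off + length(c2))
  p <- lo:hi
  p2 <- p - off
  n <- length(p)
  b1 <- rep(NA_character_, n); qq1 <- rep(-1L, n)
  i1 <- which(p >= 1L & p <= length(c1))
  b1[i1] <- c1[p[i1]]; qq1[i1] <- q1[p[i1]]
  b2 <- rep(NA_character_, n); qq2 <- rep(-1L, n)
  i2 <- which(p2 >= 1L & p2 <= length(c2))
  b2[i2] <- c2[p2[i2]]; qq2[i2] <- q2[p2[i2]]
  # disagreements take the higher-quality base (R1 on quality ties)
  take2 <- is.na(b1) | (!is.na(b2) & qq2 > qq1)
  base <- ifelse(take2, b2, b1)
  qual <- pmax(qq1, qq2)
  list(seq = paste(base, collapse = ""), qual = int_to_qual(qual))
}

# Candidate offsets for r2rc against r1 proposed by exact k-mer probes, plus an
# exhaustive scan of short suffix/prefix overlaps that probes can miss.
candidate_offsets <- function(s1, c1, c2, min_overlap, k = 12L) {
  n1 <- length(c1); n2 <- length(c2)
  offs <- integer(0)
  probe_starts <- seq(1L, max(1L, n2 - k + 1L), by = 4L)
  if (length(probe_starts) > 40L) probe_starts <- probe_starts[seq_len(40L)]
  for (ps in probe_starts) {
    pk <- min(k, n2 - ps + 1L)
    if (pk < 8L) break
    probe <- paste(c2[ps:(ps + pk - 1L)], collapse = "")
    m <- gregexpr(probe, s1, fixed = TRUE)[[1L]]
    if (m[1L] != -1L) offs <- c(offs, as.integer(m) - ps)
    if (length(offs) >= 1L && ps > 20L) break
  }
  # short true overlaps: r2rc prefix vs r1 suffix and vice versa
  hi_short <- min(2L * k, n1, n2)
  if (hi_short >= min_overlap + 1L) {
    short <- (min_overlap + 1L):hi_short
    offs <- c(offs, n1 - short, short - n2)
  }
  unique(offs[offs > -n2 & offs < n1])
}

#' Merge overlapping paired-end reads
#'
#' R2 is reverse-complemented, the best ungapped overlap against R1 is located, and
#' pairs whose overlap exceeds `min_overlap` bases (strictly) with a mismatch fraction
#' at most `max_mismatch_fraction` are merged into a consensus read. Disagreements take
#' the higher-quality base; consensus quality is the maximum of the two.
#'
#' @param r1,r2 Read-set data frames of equal length (mates in the same order).
#' @param min_overlap Overlaps must be strictly greater than this (default 10 bp).
#' @param max_mismatch_fraction Maximum allowed mismatch fraction in the overlap.
#' @return A list with `merged` (read-set data frame) and `unmerged` (list with `r1`,
#'   `r2` read-set data frames of the pairs that failed to merge).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_fraction = 0.2) {
  check_reads(r1); check_reads(r2)
  stopifnot(nrow(r1) == nrow(r2))
  n <- nrow(r1)
  if (n == 0L)
    return(list(merged = empty_reads(), unmerged = list(r1 = empty_reads(), r2 = empty_reads())))
  r2rc_seq <- revcomp(r2$seq)
  r2rc_qual <- str_rev(r2$qual)
  merged_idx <- logical(n)
  m_seq <- character(n); m_qual <- character(n)
  c1_all <- seq_chars(r1$seq); c2_all <- seq_chars(r2rc_seq)
  for (i in seq_len(n)) {
    c1 <- c1_all[[i]]; c2 <- c2_all[[i]]
    q1 <- qual_to_int(r1$qual[i]); q2 <- qual_to_int(r2rc_qual[i])
    best_off <- NA_integer_; best_score <- -Inf
    for (off in candidate_offsets(r1$seq[i], c1, c2, min_overlap)) {
      st <- overlap_stats(c1, c2, off)
      if (st["ov"] <= min_overlap) next
      if (st["mism"] / st["ov"] > max_mismatch_fraction) next
      score <- st["ov"] - 2L * st["mism"]
      if (score > best_score) {
        best_score <- score; best_off <- off
      }
    }
    if (!is.na(best_off)) {
      mg <- merge_at_offset(c1, q1, c2, q2, best_off)
      merged_idx[i] <- TRUE
      m_seq[i] <- mg$seq; m_qual[i] <- mg$qual
    }
  }
  list(merged = data.frame(id = r1$id[merged_idx], seq = m_seq[merged_idx],
                           qual = m_qual[merged_idx], stringsAsFactors = FALSE),
       unmerged = list(r1 = r1[!merged_idx, , drop = FALSE],
                       r2 = r2[!merged_idx, , drop = FALSE]))
}

dedup_stats <- function(n_before, n_after) {
  list(n_before = n_before, n_after = n_after,
       duplication_rate = duplication_rate(n_before, n_after))
}

#' Exact-sequence deduplication
#'
#' Keeps one representative per distinct sequence; for pairs, per distinct ordered
#' concatenation of the two mate sequences (qualities are ignored by the key). The
#' representative is the member with the highest total base quality; ties go to the
#' first seen.
#'
#' @param reads Read-set data frame (single reads or R1 of pairs).
#' @param reads2 Optional R2 read-set data frame (same order as `reads`).
#' @return A list with `reads` (and `reads2` if paired) and `stats` (fields `n_before`,
#'   `n_after`, `duplication_rate`).
#' @export
dedup_exact <- function(reads, reads2 = NULL) {
  check_reads(reads)
  n <- nrow(reads)
  if (!is.null(reads2)) {
    check_reads(reads2)
    stopifnot(nrow(reads2) == n)
  }
  if (n == 0L) {
    out <- list(reads = reads, stats = dedup_stats(0L, 0L))
    if (!is.null(reads2)) out$reads2 <- reads2
    return(out)
  }
  key <- if (is.null(reads2)) reads$seq else paste(reads$seq, reads2$seq, sep = "|")
  tq <- vapply(reads$qual, function(q) sum(qual_to_int(q)), numeric(1), USE.NAMES = FALSE)
  if (!is.null(reads2))
    tq <- tq + vapply(reads2$qual, function(q) sum(qual_to_int(q)), numeric(1),
                      USE.NAMES = FALSE)
  # stable selection of the highest-quality member per key (first seen wins ties)
  ord <- order(match(key, unique(key)), -tq, seq_len(n))
  sel <- ord[!duplicated(key[ord])]
  sel <- sort(sel)
  out <- list(reads = reads[sel, , drop = FALSE],
              stats = dedup_stats(n, length(sel)))
  if (!is.null(reads2)) out$reads2 <- reads2[sel, , drop = FALSE]
  rownames(out$reads) <- NULL
  out
}

#' Coordinate-class deduplication
#'
#' Keeps one representative per distinct (start, end, strand) class regardless of
#' sequence content, mirroring coordinate-based duplicate-removal tools. The
#' representative is the member with the highest total base quality; ties go to the
#' first seen.
#'
#' @param aln Alignment data frame (see [align_reads()]).
#' @return A list with `aln` (retained alignments) and `stats`.
#' @export
dedup_by_coordinates <- function(aln) {
  aln <- check_alignments(aln)
  n <- nrow(aln)
  if (n == 0L) return(list(aln = aln, stats = dedup_stats(0L, 0L)))
  key <- paste(aln$start, aln$end, aln$strand, sep = ":")
  tq <- vapply(aln$qual, function(q) sum(qual_to_int(q)), numeric(1), USE.NAMES = FALSE)
  ord <- order(match(key, unique(key)), -tq, seq_len(n))
  sel <- sort(ord[!duplicated(key[ord])])
  out <- aln[sel, , drop = FALSE]
  rownames(out) <- NULL
  list(aln = out, stats = dedup_stats(n, length(sel)))
}

#' Duplication rate
#'
#' One minus the number of reads after deduplication divided by the number before.
#'
#' @param n_before,n_after Read counts before/after deduplication.
#' @return Fraction in \[0, 1\]; defined as 0 (with a warning) when `n_before` is 0.
#' @export
duplication_rate <- function(n_before, n_after) {
  stopifnot(n_after <= n_before)
  if (n_before == 0) {
    warning("duplication rate undefined for zero reads; reporting 0")
    return(0)
  }
  1 - n_after / n_before
}
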