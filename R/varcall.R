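# Pileup construction, variant and IUPAC mixed-base calling in rCRS numbering,
# HSD haplotype emission, mixed-base report and the damaged-vs-all contamination check.
#
# Calling is SNV-only by construction (ungapped alignments, per-column base counts).
# A site qualifies when its quality-filtered depth reaches min_depth and it lies
# outside the poly-C tract rCRS 303-315 (excluded for alignment complexity). Bases at
# frequency >= 30% are "observed alleles": a single non-reference allele above 70% is a
# substitution; two or more observed alleles each within [30%, 70%] are a mixed base,
# reported with the IUPAC ambiguity symbol over the observed alleles.

IUPAC_TABLE <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' IUPAC ambiguity symbol for a set of bases
#'
#' @param bases Non-empty character vector, subset of A/C/G/T.
#' @return Single IUPAC symbol.
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set")
  if (!all(bases %in% DNA_BASES)) stop("bases must be A/C/G/T")
  unname(IUPAC_TABLE[paste(sort(bases), collapse = "")])
}

#' Build a base-count pileup from alignments
#'
#' Counts A/C/G/T per linear reference position over all alignments, in forward
#' orientation; bases with quality below `min_base_quality` and non-ACGT bases are
#' excluded from their column.
#'
#' @param aln Alignment data frame (deduplicated, mapping-quality-filtered).
#' @param lin The `linearized_ncr`.
#' @param min_base_quality Minimum Phred quality for a base to be counted (default 20).
#' @return An object of class `pileup`: list with `counts` (4 x L matrix, rows
#'   A/C/G/T) and `depth` (length-L vector of column sums).
#' @export
build_pileup <- function(aln, lin, min_base_quality = 20L) {
  aln <- check_alignments(aln)
  stopifnot(inherits(lin, "linearized_ncr"))
  L <- lin$length
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  if (nrow(aln) > 0L) {
    neg <- aln$strand == "-"
    fwd_seq <- aln$seq; fwd_qual <- aln$qual
    fwd_seq[neg] <- revcomp(aln$seq[neg])
    fwd_qual[neg] <- str_rev(aln$qual[neg])
    for (i in seq_len(nrow(aln))) {
      chars <- strsplit(fwd_seq[i], "", fixed = TRUE)[[1L]]
      quals <- qual_to_int(fwd_qual[i])
      pos <- aln$start[i]:aln$end[i]
      ok <- quals >= min_base_quality & chars %in% DNA_BASES
      if (any(ok)) {
        ij <- cbind(match(chars[ok], DNA_BASES), pos[ok])
        # duplicate indices within one read cannot occur (ungapped, one base/position)
        counts[ij] <- counts[ij] + 1L
      }
    }
  }
  structure(list(counts = counts, depth = colSums(counts), length = L),
            class = "pileup")
}

#' Covered intervals at a minimum depth
#'
#' Maximal runs of linear positions with depth >= `min_depth`, mapped to circular
#' (rCRS) numbering and split at the origin, rendered like `"16013-16569;1-592"`.
#'
#' @param pileup A `pileup`.
#' @param lin The `linearized_ncr`.
#' @param min_depth Minimum depth (default 10).
#' @return A list with `intervals` (data frame `rcrs_start`, `rcrs_end`, in NCR
#'   traversal order) and `range_string`.
#' @export
covered_intervals <- function(pileup, lin, min_depth = 10L) {
  stopifnot(inherits(pileup, "pileup"), inherits(lin, "linearized_ncr"))
  ok <- pileup$depth >= min_depth
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  out_s <- integer(0); out_e <- integer(0)
  head_len <- lin$circular_length - lin$cut_start + 1L
  for (j in seq_along(starts)) {
    a <- starts[j]; b <- ends[j]
    if (a <= head_len && b > head_len) {
      out_s <- c(out_s, to_circular(lin, a), 1L)
      out_e <- c(out_e, lin$circular_length, to_circular(lin, b))
    } else {
      out_s <- c(out_s, to_circular(lin, a))
      out_e <- c(out_e, to_circular(lin, b))
    }
  }
  intervals <- data.frame(rcrs_start = out_s, rcrs_end = out_e)
  list(intervals = intervals,
       range_string = paste(paste0(out_s, "-", out_e), collapse = ";"))
}

#' Call variants and mixed bases from a pileup
#'
#' @param pileup A `pileup`.
#' @param lin The `linearized_ncr` (for rCRS renumbering).
#' @param ref The `circular_reference` used as calling baseline (the canonical
#'   reference, not the sample).
#' @param min_depth Minimum quality-filtered depth for a site to qualify (default 10).
#' @param min_freq Minimum allele frequency to observe an allele (default 0.30).
#' @param mixed_upper Upper bound of the mixed-base window (default 0.70); a single
#'   non-reference allele strictly above it is a substitution.
#' @param excluded_region rCRS interval excluded from calling (default 303-315).
#' @return Data frame of calls: `rcrs_pos`, `lin_pos`, `ref_base`, `type`
#'   ("substitution"/"mixed"), `call` (base or IUPAC symbol), `alleles`
#'   (comma-separated observed alleles), `depth`, `alt_base`, `alt_count`, `alt_pct`.
#' @export
call_variants <- function(pileup, lin, ref, min_depth = 10L, min_freq = 0.30,
                          mixed_upper = 0.70, excluded_region = c(303L, 315L)) {
  stopifnot(inherits(pileup, "pileup"), inherits(lin, "linearized_ncr"),
            inherits(ref, "circular_reference"))
  empty <- data.frame(rcrs_pos = integer(0), lin_pos = integer(0),
                      ref_base = character(0), type = character(0),
                      call = character(0), alleles = character(0),
                      depth = integer(0), alt_base = character(0),
                      alt_count = integer(0), alt_pct = numeric(0),
                      stringsAsFactors = FALSE)
  qualify <- which(pileup$depth >= min_depth)
  if (length(qualify) == 0L) return(empty)
  rcrs_pos <- to_circular(lin, qualify)
  excl <- rcrs_pos >= excluded_region[1L] & rcrs_pos <= excluded_region[2L]
  qualify <- qualify[!excl]; rcrs_pos <- rcrs_pos[!excl]
  if (length(qualify) == 0L) return(empty)
  ref_base <- substring(ref$sequence, rcrs_pos, rcrs_pos)
  rows <- vector("list", length(qualify))
  for (j in seq_along(qualify)) {
    p <- qualify[j]
    rb <- ref_base[j]
    if (!rb %in% DNA_BASES) {
      warning("reference base ", rb, " at rCRS ", rcrs_pos[j], "; position skipped")
      next
    }
    cnt <- pileup$counts[, p]
    depth <- sum(cnt)
    freq <- cnt / depth
    observed <- DNA_BASES[freq >= min_freq]
    non_ref <- setdiff(observed, rb)
    if (length(non_ref) == 0L) next
    alt <- non_ref[which.max(freq[non_ref])]
    if (length(non_ref) == 1L && freq[alt] > mixed_upper) {
      rows[[j]] <- data.frame(rcrs_pos = rcrs_pos[j], lin_pos = p, ref_base = rb,
                              type = "substitution", call = alt,
                              alleles = alt, depth = depth, alt_base = alt,
                              alt_count = cnt[alt], alt_pct = 100 * freq[alt],
                              stringsAsFactors = FALSE)
    } else if (length(observed) >= 2L &&
               all(freq[observed] >= min_freq & freq[observed] <= mixed_upper)) {
      rows[[j]] <- data.frame(rcrs_pos = rcrs_pos[j], lin_pos = p, ref_base = rb,
                              type = "mixed", call = iupac_code(observed),
                              alleles = paste(observed, collapse = ","),
                              depth = depth, alt_base = alt,
                              alt_count = cnt[alt], alt_pct = 100 * freq[alt],
                              stringsAsFactors = FALSE)
    } else if (length(non_ref) >= 1L && freq[alt] > mixed_upper) {
      # dominant non-reference allele above the window with further minor alleles:
      # still a substitution of the dominant allele
      rows[[j]] <- data.frame(rcrs_pos = rcrs_pos[j], lin_pos = p, ref_base = rb,
                              type = "substitution", call = alt,
                              alleles = paste(observed, collapse = ","),
                              depth = depth, alt_base = alt,
                              alt_count = cnt[alt], alt_pct = 100 * freq[alt],
                              stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$lin_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Haplotype tokens from variant calls
#'
#' Tokens are `<rCRS position><base or IUPAC symbol>` (e.g. `16126C`, `152Y`), ordered
#' along the NCR traversal 16013 -> 16569 -> 1 -> 592 (i.e. by linear position).
#'
#' @param calls Data frame from [call_variants()].
#' @return Character vector of tokens.
#' @export
haplotype_tokens <- function(calls) {
  if (nrow(calls) == 0L) return(character(0))
  calls <- calls[order(calls$lin_pos), , drop = FALSE]
  paste0(calls$rcrs_pos, calls$call)
}

#' Format / write / read HSD records
#'
#' One tab-separated line per sample: id, covered range, `"?"` (haplogroup unknown;
#' classification is delegated to external tools), then one field per haplotype token.
#'
#' @param id Sample identifier(s).
#' @param range_string Covered-range string(s), e.g. `"16013-16569;1-592"`.
#' @param tokens Character vector of tokens (or list of such vectors for several
#'   samples).
#' @return `format_hsd` returns the line(s); `write_hsd` writes them (with a header)
#'   and returns the path; `read_hsd` parses a file back into a data frame with
#'   columns `id`, `range`, `haplogroup`, `haplotype`.
#' @export
format_hsd <- function(id, range_string, tokens) {
  if (!is.list(tokens)) tokens <- list(tokens)
  stopifnot(length(id) == length(tokens), length(range_string) == length(tokens))
  vapply(seq_along(id), function(i) {
    paste(c(id[i], range_string[i], "?", tokens[[i]]), collapse = "\t")
  }, character(1))
}

#' @rdname format_hsd
#' @param path Output/input path.
#' @export
write_hsd <- function(id, range_string, tokens, path) {
  writeLines(format_hsd(id, range_string, tokens), path)
  invisible(path)
}

#' @rdname format_hsd
#' @export
read_hsd <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, character(1), 1L),
             range = vapply(parts, `[`, character(1), 2L),
             haplogroup = vapply(parts, `[`, character(1), 3L),
             haplotype = vapply(parts, function(p)
               paste(p[-(1:3)], collapse = " "), character(1)),
             stringsAsFactors = FALSE)
}

#' Mixed-base report rows
#'
#' One row per mixed-base call: sample id, rCRS position, alternative base, depth,
#' alternative-base count and percentage. Only mixtures whose alternative-base
#' percentage lies within \[30, 70\] appear (guaranteed by the caller's window).
#'
#' @param sample_id Sample identifier.
#' @param calls Data frame from [call_variants()].
#' @return Data frame with columns `sample_id`, `position`, `alt_base`, `depth`,
#'   `alt_count`, `alt_pct`.
#' @export
mixed_base_report <- function(sample_id, calls) {
  mx <- calls[calls$type == "mixed", , drop = FALSE]
  out <- data.frame(sample_id = rep(sample_id, nrow(mx)),
                    position = mx$rcrs_pos, alt_base = mx$alt_base,
                    depth = mx$depth, alt_count = mx$alt_count,
                    alt_pct = mx$alt_pct, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Contamination check: damaged-only vs all-reads profiles
#'
#' Compares the haplotype called from all useful reads with the haplotype called from
#' damaged reads only (the latter contains essentially only endogenous ancient
#' molecules). A discordant site is a position covered at `min_depth` in both profiles
#' where the calls differ. The flag is raised when at least one discordant site exists
#' or when the all-reads profile contains more than one mixed base.
#'
#' @param calls_all,calls_damaged Call data frames from [call_variants()].
#' @param pileup_all,pileup_damaged The corresponding pileups.
#' @param mixed_count Number of mixed bases in the all-reads profile.
#' @param min_depth Minimum depth for a site to be comparable (default 10).
#' @return A list with `flag` (`"possible contamination"`, `"no contamination
#'   detected"`, or `"not evaluable"`), `n_discordant`, `discordant` (data frame of
#'   discordant sites) and `mixed_count`.
#' @export
contamination_check <- function(calls_all, calls_damaged, pileup_all, pileup_damaged,
                                mixed_count, min_depth = 10L) {
  stopifnot(inherits(pileup_all, "pileup"), inherits(pileup_damaged, "pileup"))
  if (all(pileup_damaged$depth < min_depth))
    return(list(flag = "not evaluable", n_discordant = NA_integer_,
                discordant = NULL, mixed_count = mixed_count))
  joint <- which(pileup_all$depth >= min_depth & pileup_damaged$depth >= min_depth)
  call_at <- function(calls, pos) {
    m <- match(pos, calls$lin_pos)
    ifelse(is.na(m), ".", calls$call[m])  # "." = reference (no call)
  }
  ca <- call_at(calls_all, joint)
  cd <- call_at(calls_damaged, joint)
  diff <- ca != cd
  discordant <- data.frame(lin_pos = joint[diff],
                           call_all = ca[diff], call_damaged = cd[diff],
                           stringsAsFactors = FALSE)
  flag <- if (sum(diff) >= 1L || mixed_count > 1L) "possible contamination"
  else "no contamination detected"
  list(flag = flag, n_discordant = sum(diff), discordant = discordant,
       mixed_count = mixed_count)
}

#' Assemble a per-sample summary row
#'
#' @param sample_id Sample identifier.
#' @param n_initial Number of raw input reads (both mates counted).
#' @param dup_rate Duplication rate fraction from exact-sequence deduplication.
#' @param useful_aln Mapping-quality-filtered alignment data frame.
#' @param damage_stats Damage statistics from [extract_damaged()].
#' @param pileup All-reads pileup.
#' @param panel An `amplicon_panel`.
#' @param n_mixed Number of mixed bases.
#' @param range_string Covered-range string.
#' @param tokens Haplotype tokens.
#' @return One-row data frame with the pipeline's summary fields (`haplogroup` is
#'   always `"?"`; classification is external).
#' @export
sample_summary <- function(sample_id, n_initial, dup_rate, useful_aln, damage_stats,
                           pileup, panel, n_mixed, range_string, tokens) {
  span <- attr(panel, "span")
  depth <- pileup$depth[span[1]:span[2]]
  data.frame(sample_id = sample_id,
             n_initial = n_initial,
             duplication_rate = dup_rate,
             n_useful = nrow(useful_aln),
             pct_useful = if (n_initial > 0) 100 * nrow(useful_aln) / n_initial else 0,
             mean_depth = mean(depth),
             mean_mapq = if (nrow(useful_aln) > 0) mean(useful_aln$mapq) else NA_real_,
             n_damaged = damage_stats$n_damaged,
             pct_damaged = damage_stats$pct_damaged,
             n_mixed = n_mixed,
             haplogroup = "?",
             range = range_string,
             haplotype = paste(tokens, collapse = " "),
             stringsAsFactors = FALSE)
}
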