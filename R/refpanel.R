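# Circular-reference linearization, coordinate remapping and amplicon panel geometry.
#
# The human mtDNA is circular; reads spanning the replication origin misalign against a
# naively linear reference. The control-region workflow therefore cuts the circle inside
# the coding region and renumbers, so that the whole non-coding region (NCR) becomes one
# contiguous linear sequence. All interface coordinates are 1-based closed intervals.

#' Create a circular reference sequence
#'
#' Wraps a DNA sequence (e.g. the 16,569 bp revised Cambridge Reference Sequence, rCRS)
#' as a circular reference object.
#'
#' @param sequence DNA string; alphabet A/C/G/T/N. Lower case is accepted and upcased.
#' @param id Sequence identifier.
#' @return An object of class `circular_reference` with fields `id`, `sequence`, `length`.
#' @export
circular_reference <- function(sequence, id = "chrM") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("reference alphabet must be A/C/G/T/N")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "circular_reference")
}

#' Read a single-record reference FASTA as a circular reference
#'
#' @param path Path to a FASTA file containing exactly one sequence.
#' @return A `circular_reference`.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("reference FASTA must contain exactly one sequence")
  id <- sub("\\s.*$", "", names(ss)[1L])
  circular_reference(as.character(ss[[1L]]), id = id)
}

#' @export
print.circular_reference <- function(x, ...) {
  cat("Circular reference", x$id, "-", x$length, "bp\n")
  invisible(x)
}

#' Linearize a circular reference across the origin
#'
#' Cuts the circle so that `cut_start` becomes linear position 1 and the sequence runs
#' through the origin to `cut_end`. With the defaults (15901, 700) this yields the
#' 1,369 bp window containing the whole mtDNA NCR, with rCRS 15901 at linear position 1.
#'
#' @param ref A `circular_reference`.
#' @param cut_start 1-based circular position that becomes linear position 1 (default 15901).
#' @param cut_end 1-based circular position at which the window ends (default 700).
#'   Must be smaller than `cut_start`: the window must wrap the origin.
#' @return An object of class `linearized_ncr` with fields `id`, `sequence`, `length`,
#'   `cut_start`, `cut_end`, `circular_length`.
#' @export
linearize_reference <- function(ref, cut_start = 15901L, cut_end = 700L) {
  stopifnot(inherits(ref, "circular_reference"))
  cut_start <- as.integer(cut_start); cut_end <- as.integer(cut_end)
  L <- ref$length
  if (cut_start < 1L || cut_start > L || cut_end < 1L || cut_end > L)
    stop("cut positions out of range [1, ", L, "]")
  if (cut_start <= cut_end)
    stop("cut_start must exceed cut_end (the window must wrap the origin)")
  seq_lin <- paste0(substr(ref$sequence, cut_start, L),
                    substr(ref$sequence, 1L, cut_end))
  structure(list(id = paste0(ref$id, "_lin"), sequence = seq_lin,
                 length = nchar(seq_lin), cut_start = cut_start,
                 cut_end = cut_end, circular_length = L),
            class = "linearized_ncr")
}

#' @export
print.linearized_ncr <- function(x, ...) {
  cat("Linearized window ", x$cut_start, "..", x$circular_length, ";1..", x$cut_end,
      " -> 1..", x$length, " (", x$length, " bp)\n", sep = "")
  invisible(x)
}

#' Map positions between circular and linear coordinates
#'
#' The linearization induces a bijection between the circular window
#' `{cut_start..L} U {1..cut_end}` and linear `{1..length}`; `map_position` applies it in
#' either direction. Vectorized over `pos`.
#'
#' @param lin A `linearized_ncr`.
#' @param pos Integer vector of positions.
#' @param direction `"to_linear"` (circular -> linear) or `"to_circular"`.
#' @return Integer vector of mapped positions.
#' @export
map_position <- function(lin, pos, direction = c("to_linear", "to_circular")) {
  direction <- match.arg(direction)
  stopifnot(inherits(lin, "linearized_ncr"))
  pos <- as.integer(pos)
  L <- lin$circular_length
  head_len <- L - lin$cut_start + 1L
  if (direction == "to_linear") {
    out <- integer(length(pos))
    hi <- pos >= lin$cut_start & pos <= L
    lo <- pos >= 1L & pos <= lin$cut_end
    if (any(!hi & !lo))
      stop("position(s) outside NCR window (",
           lin$cut_end + 1L, "..", lin$cut_start - 1L, " are not covered): ",
           paste(pos[!hi & !lo], collapse = ", "))
    out[hi] <- pos[hi] - lin$cut_start + 1L
    out[lo] <- head_len + pos[lo]
    out
  } else {
    if (any(pos < 1L | pos > lin$length))
      stop("linear position(s) out of range [1, ", lin$length, "]")
    ifelse(pos <= head_len, pos + lin$cut_start - 1L, pos - head_len)
  }
}

#' @rdname map_position
#' @export
to_linear <- function(lin, pos) map_position(lin, pos, "to_linear")

#' @rdname map_position
#' @export
to_circular <- function(lin, pos) map_position(lin, pos, "to_circular")

# The ten amplicons of the PowerSeq CRM Nested panel, in circular (rCRS) numbering.
# Amplicon 5 wraps the origin (16474..30).
POWERSEQ_CRM_COORDS <- data.frame(
  index = 1:10,
  rcrs_start = c(16013L, 16116L, 16223L, 16387L, 16474L, 16555L, 136L, 246L, 342L, 429L),
  rcrs_end   = c(16126L, 16225L, 16408L, 16486L,    30L,   152L, 257L, 364L, 436L, 592L)
)

panel_from_coords <- function(coords, lin, primer_trim_5p = 25L, primer_trim_3p = 5L) {
  lin_start <- map_position(lin, coords$rcrs_start, "to_linear")
  lin_end <- map_position(lin, coords$rcrs_end, "to_linear")
  if (any(lin_start > lin_end))
    stop("amplicon start falls after its end in linear coordinates")
  pan <- data.frame(index = as.integer(coords$index),
                    rcrs_start = as.integer(coords$rcrs_start),
                    rcrs_end = as.integer(coords$rcrs_end),
                    lin_start = lin_start, lin_end = lin_end,
                    insert_start = lin_start + as.integer(primer_trim_5p),
                    insert_end = lin_end - as.integer(primer_trim_3p),
                    stringsAsFactors = FALSE)
  if (any(pan$insert_start > pan$insert_end))
    stop("primer trims exceed amplicon length")
  pan <- pan[order(pan$lin_start), , drop = FALSE]
  rownames(pan) <- NULL
  class(pan) <- c("amplicon_panel", "data.frame")
  attr(pan, "span") <- c(min(pan$lin_start), max(pan$lin_end))
  pan
}

#' Default amplicon panel (PowerSeq CRM Nested, 10 amplicons)
#'
#' Converts the ten published amplicon intervals (spanning rCRS 16013-592, amplicon 5
#' wrapping the origin as 16474-30) to linear coordinates on the given linearized
#' reference. Primer sequences are proprietary, so the primer-trimmed insert of each
#' amplicon is derived from fixed end trims (25 bp at the 5' end, 5 bp at the 3' end,
#' in molecule orientation).
#'
#' @param lin A `linearized_ncr` whose window contains all panel coordinates.
#' @param primer_trim_5p,primer_trim_3p Fixed primer-trim lengths in bp.
#' @return An `amplicon_panel` data frame with columns `index`, `rcrs_start`, `rcrs_end`,
#'   `lin_start`, `lin_end`, `insert_start`, `insert_end`, sorted by linear start.
#' @export
default_panel <- function(lin, primer_trim_5p = 25L, primer_trim_3p = 5L) {
  panel_from_coords(POWERSEQ_CRM_COORDS, lin, primer_trim_5p, primer_trim_3p)
}

#' Read an amplicon panel definition from a plain-text file
#'
#' Each non-comment line lists `index rcrs_start rcrs_end` (whitespace-separated).
#'
#' @param path Path to the panel file.
#' @inheritParams default_panel
#' @return An `amplicon_panel`.
#' @export
read_panel <- function(path, lin, primer_trim_5p = 25L, primer_trim_3p = 5L) {
  coords <- utils::read.table(path, header = FALSE, comment.char = "#",
                              col.names = c("index", "rcrs_start", "rcrs_end"))
  panel_from_coords(coords, lin, primer_trim_5p, primer_trim_3p)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("Amplicon panel:", nrow(x), "amplicons, linear span",
      attr(x, "span")[1], "-", attr(x, "span")[2], "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Assign read intervals to amplicons by maximal insert overlap
#'
#' Each interval is assigned to the amplicon whose primer-trimmed insert overlaps it the
#' most; ties are broken toward the lower amplicon index; zero overlap yields `NA`.
#' Vectorized over intervals.
#'
#' @param panel An `amplicon_panel`.
#' @param start,end Integer vectors of 1-based closed linear intervals.
#' @return Integer vector of amplicon indices (`NA` where no insert overlaps).
#' @export
assign_amplicon <- function(panel, start, end) {
  stopifnot(inherits(panel, "amplicon_panel"), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) stop("empty interval(s): end < start")
  n <- length(start)
  if (n == 0L) return(integer(0))
  # overlap matrix: intervals x amplicons (columns in ascending amplicon-index order so
  # that max.col's "first" tie-break realises the lower-index rule)
  ord <- order(panel$index)
  ov <- outer(end, panel$insert_end[ord], pmin) - outer(start, panel$insert_start[ord], pmax) + 1L
  ov[ov < 0L] <- 0L
  best <- max.col(ov, ties.method = "first")
  idx <- panel$index[ord][best]
  idx[ov[cbind(seq_len(n), best)] == 0L] <- NA_integer_
  idx
}
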