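# Synthetic degraded-amplicon library simulator.
#
# Emulates the processes an amplicon library from a degraded sample goes through:
# template molecules spanning fixed primer-to-primer intervals, cytosine deamination
# concentrated at molecule ends (C->T from the 5' end, G->A from the 3' end) applied
# once per template so PCR duplicates inherit it, geometric PCR duplication, per-read
# sequencing error at a fixed rate, adapter read-through for short inserts, and optional
# contamination by a second undamaged profile. Every emitted read carries a truth row.


#' Deamination damage model for simulation
#'
#' C->T changes are applied at 5'-distance `z` (0-based) with probability
#' `p_background + p_max * lambda^z`; G->A changes mirror this from the 3' end.
#'
#' @param p_max Terminal deamination magnitude.
#' @param lambda Geometric decay per base, in (0, 1).
#' @param p_background Position-independent deamination probability.
#' @return An object of class `sim_damage_model`.
#' @export
sim_damage_model <- function(p_max = 0.3, lambda = 0.3, p_background = 0.01) {
  stopifnot(p_max >= 0, p_background >= 0, p_max + p_background <= 1,
            lambda > 0, lambda < 1)
  structure(list(p_max = p_max, lambda = lambda, p_background = p_background),
            class = "sim_damage_model")
}

#' Simulation configuration
#'
#' @param molecules_per_amplicon Integer vector, one count per panel amplicon.
#' @param duplication_mean Mean number of extra PCR duplicates per molecule
#'   (geometric); 0 disables duplication.
#' @param error_rate Per-base sequencing error probability; emitted as a constant
#'   Phred quality `round(-10*log10(error_rate))` (Q40 when 0).
#' @param read_length Read length of the simulated paired-end run (>= 30).
#' @param contaminant_fraction Probability that a molecule is drawn from the
#'   contaminant profile instead of the endogenous one.
#' @param seed Integer seed driving all randomness of the simulator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(molecules_per_amplicon, duplication_mean = 1,
                       error_rate = 0.001, read_length = 150L,
                       contaminant_fraction = 0, seed = 1L) {
  stopifnot(all(molecules_per_amplicon >= 0), duplication_mean >= 0,
            error_rate >= 0, error_rate <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  if (read_length < 30L)
    stop("read_length below the pipeline minimum of 30 bp")
  structure(list(molecules_per_amplicon = as.integer(molecules_per_amplicon),
                 duplication_mean = duplication_mean, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 contaminant_fraction = contaminant_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a seeded synthetic circular reference
#'
#' Uniform-random A/C/G/T sequence used as a stand-in reference in tests and
#' simulations (the real rCRS is user-supplied via [read_reference_fasta()]).
#'
#' @param length Sequence length (default 16569, the rCRS length).
#' @param seed Integer seed.
#' @return A `circular_reference`.
#' @export
synthetic_circular_reference <- function(length = 16569L, seed = 1L) {
  old <- seed_guard(seed)
  on.exit(old())
  circular_reference(paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""),
                     id = "synthetic_chrM")
}

# Set the RNG reproducibly and return a restorer.
seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }
}

# Parse tokens like "16126C" / "152Y" into positions and bases.
parse_variant_tokens <- function(tokens) {
  if (length(tokens) == 0L)
    return(data.frame(pos = integer(0), base = character(0)))
  m <- regmatches(tokens, regexec("^([0-9]+)([A-Z])$", tokens))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed variant token(s): ", paste(tokens[bad], collapse = ", "))
  data.frame(pos = as.integer(vapply(m, `[`, character(1), 2L)),
             base = vapply(m, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Plant haplotype variants into a circular reference
#'
#' @param ref A `circular_reference`.
#' @param tokens Character vector of variant tokens such as `"16126C"` (circular,
#'   rCRS-style numbering). The planted base must differ from the reference base.
#' @return A `circular_reference` differing from `ref` exactly at the token positions.
#' @export
plant_haplotype <- function(ref, tokens) {
  stopifnot(inherits(ref, "circular_reference"))
  tk <- parse_variant_tokens(tokens)
  if (nrow(tk) == 0L) return(ref)
  if (any(tk$pos < 1L | tk$pos > ref$length)) stop("token position out of range")
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  same <- chars[tk$pos] == tk$base
  if (any(same))
    stop("token base equals the reference base at: ",
         paste(tokens[same], collapse = ", "))
  chars[tk$pos] <- tk$base
  circular_reference(paste(chars, collapse = ""), id = ref$id)
}

# Apply deamination to one molecule sequence (molecule orientation). Returns the
# damaged sequence and the 1-based damaged positions within the molecule.
apply_deamination <- function(chars, dmg) {
  n <- length(chars)
  z5 <- seq_len(n) - 1L          # 0-based distance from 5' end
  z3 <- n - seq_len(n)           # 0-based distance from 3' end
  p_ct <- dmg$p_background + dmg$p_max * dmg$lambda^z5
  p_ga <- dmg$p_background + dmg$p_max * dmg$lambda^z3
  u <- stats::runif(n)
  hit_c <- chars == "C" & u < p_ct
  hit_g <- chars == "G" & u < p_ga
  chars[hit_c] <- "T"
  chars[hit_g] <- "A"
  list(chars = chars, pos = which(hit_c | hit_g))
}

#' Simulate template molecules over an amplicon panel
#'
#' Each molecule spans one amplicon's full primer-to-primer interval on a random strand.
#' Deamination is applied once per template molecule, so all PCR duplicates of a molecule
#' later inherit identical damage. With `contaminant_fraction > 0` a molecule is drawn
#' from `contaminant_ref` (left undamaged) with that probability.
#'
#' @param ref Endogenous `circular_reference` (typically with a planted haplotype).
#' @param panel An `amplicon_panel` on the linearization of `ref`.
#' @param dmg A `sim_damage_model`.
#' @param cfg A `sim_config`.
#' @param lin Optional pre-computed `linearized_ncr` of `ref` (defaults to the standard
#'   15901..700 linearization).
#' @param contaminant_ref Optional contaminant `circular_reference` (same length).
#' @return A data frame (class `sim_molecules`) with one row per molecule: `molecule_id`,
#'   `amplicon`, `strand`, `lin_start`, `lin_end`, `seq` (damaged, molecule orientation),
#'   `damage_pos` (comma-separated molecule positions), `n_damage`, `origin`.
#' @export
simulate_molecules <- function(ref, panel, dmg, cfg, lin = NULL,
                               contaminant_ref = NULL) {
  stopifnot(inherits(ref, "circular_reference"), inherits(panel, "amplicon_panel"),
            inherits(dmg, "sim_damage_model"), inherits(cfg, "sim_config"))
  if (nrow(panel) == 0L) stop("empty amplicon panel")
  if (length(cfg$molecules_per_amplicon) != nrow(panel))
    stop("molecules_per_amplicon length must equal the panel size")
  if (is.null(lin)) lin <- linearize_reference(ref)
  lin_cont <- if (!is.null(contaminant_ref))
    linearize_reference(contaminant_ref, lin$cut_start, lin$cut_end)
  restore <- seed_guard(cfg$seed)
  on.exit(restore())

  n_total <- sum(cfg$molecules_per_amplicon)
  amp_of <- rep(panel$index, cfg$molecules_per_amplicon)
  row_of <- rep(seq_len(nrow(panel)), cfg$molecules_per_amplicon)
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  origin <- if (!is.null(lin_cont) && cfg$contaminant_fraction > 0)
    ifelse(stats::runif(n_total) < cfg$contaminant_fraction, "contaminant", "endogenous")
  else rep("endogenous", n_total)

  seqs <- character(n_total)
  dmg_pos <- character(n_total)
  n_dmg <- integer(n_total)
  # molecules sharing an amplicon, strand and origin share a template; deamination is
  # drawn jointly per group for speed (one uniform per molecule-position)
  groups <- split(seq_len(n_total), list(row_of, strand, origin), drop = TRUE)
  for (g in groups) {
    r <- row_of[g[1L]]
    src <- if (origin[g[1L]] == "contaminant") lin_cont else lin
    s <- substr(src$sequence, panel$lin_start[r], panel$lin_end[r])
    if (strand[g[1L]] == "-") s <- revcomp(s)
    if (origin[g[1L]] != "endogenous") {
      seqs[g] <- s
      dmg_pos[g] <- ""
      next
    }
    tc <- strsplit(s, "", fixed = TRUE)[[1L]]
    len <- length(tc)
    z5 <- seq_len(len) - 1L
    p_site <- ifelse(tc == "C", dmg$p_background + dmg$p_max * dmg$lambda^z5,
                     ifelse(tc == "G",
                            dmg$p_background + dmg$p_max * dmg$lambda^rev(z5), 0))
    u <- matrix(stats::runif(length(g) * len), nrow = length(g), byrow = TRUE)
    hit <- sweep(u, 2L, p_site, "<")
    any_hit <- which(rowSums(hit) > 0L)
    seqs[g] <- s
    for (jj in any_hit) {
      chars <- tc
      pos <- which(hit[jj, ])
      chars[pos] <- ifelse(chars[pos] == "C", "T", "A")
      i <- g[jj]
      seqs[i] <- paste(chars, collapse = "")
      dmg_pos[i] <- paste(pos, collapse = ",")
      n_dmg[i] <- length(pos)
    }
  }
  out <- data.frame(molecule_id = sprintf("mol%06d", seq_len(n_total)),
                    amplicon = amp_of, strand = strand,
                    lin_start = panel$lin_start[row_of],
                    lin_end = panel$lin_end[row_of],
                    seq = seqs, damage_pos = dmg_pos, n_damage = n_dmg,
                    origin = origin, stringsAsFactors = FALSE)
  class(out) <- c("sim_molecules", "data.frame")
  out
}

# Introduce uniform sequencing errors into a character vector of bases.
apply_seq_error <- function(chars, error_rate) {
  if (error_rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < error_rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  chars
}

#' PCR-amplify molecules and sequence them as paired-end reads
#'
#' Each molecule is emitted `1 + Geometric(duplication_mean)` times. R1 reads the first
#' `read_length` bases of the molecule; R2 reads the first `read_length` bases of its
#' reverse complement. When the molecule is shorter than the read length, adapter
#' sequence is appended (read-through). Sequencing errors are independent per read copy.
#'
#' @param molecules A `sim_molecules` data frame.
#' @param cfg A `sim_config`.
#' @return A list with `r1`, `r2` (read-set data frames with columns `id`, `seq`,
#'   `qual`) and `truth` (one row per pair: `read_id`, `molecule_id`, `amplicon`,
#'   `strand`, `lin_start`, `lin_end`, `damage_pos`, `n_damage`, `n_error`, `origin`).
#' @export
amplify_and_sequence <- function(molecules, cfg) {
  stopifnot(inherits(molecules, "data.frame"), inherits(cfg, "sim_config"))
  if (nrow(molecules) == 0L) stop("no molecules to amplify")
  restore <- seed_guard(cfg$seed + 1L)
  on.exit(restore())
  rl <- cfg$read_length
  q <- if (cfg$error_rate > 0) round(-10 * log10(cfg$error_rate)) else 40L
  copies <- 1L + if (cfg$duplication_mean > 0)
    stats::rgeom(nrow(molecules), prob = 1 / (1 + cfg$duplication_mean))
  else rep(0L, nrow(molecules))

  mol_idx <- rep(seq_len(nrow(molecules)), copies)
  n_reads <- length(mol_idx)
  r1_seq <- character(n_reads); r2_seq <- character(n_reads)
  n_err <- integer(n_reads)
  mol_chars <- seq_chars(molecules$seq)
  mol_rc_chars <- seq_chars(revcomp(molecules$seq))
  ad1 <- strsplit(TRUSEQ_ADAPTER_R1, "", fixed = TRUE)[[1L]]
  ad2 <- strsplit(TRUSEQ_ADAPTER_R2, "", fixed = TRUE)[[1L]]
  for (j in seq_len(n_reads)) {
    m <- mol_idx[j]
    tmpl1 <- mol_chars[[m]]; tmpl2 <- mol_rc_chars[[m]]
    if (length(tmpl1) < rl) {
      pad <- rl - length(tmpl1)
      tmpl1 <- c(tmpl1, rep_len(ad1, pad))
      tmpl2 <- c(tmpl2, rep_len(ad2, pad))
    } else {
      tmpl1 <- tmpl1[seq_len(rl)]
      tmpl2 <- tmpl2[seq_len(rl)]
    }
    s1 <- apply_seq_error(tmpl1, cfg$error_rate)
    s2 <- apply_seq_error(tmpl2, cfg$error_rate)
    n_err[j] <- sum(s1 != tmpl1) + sum(s2 != tmpl2)
    r1_seq[j] <- paste(s1, collapse = "")
    r2_seq[j] <- paste(s2, collapse = "")
  }
  ids <- sprintf("read%07d", seq_len(n_reads))
  qual <- strrep(intToUtf8(q + 33L), rl)
  truth <- data.frame(read_id = ids,
                      molecule_id = molecules$molecule_id[mol_idx],
                      amplicon = molecules$amplicon[mol_idx],
                      strand = molecules$strand[mol_idx],
                      lin_start = molecules$lin_start[mol_idx],
                      lin_end = molecules$lin_end[mol_idx],
                      damage_pos = molecules$damage_pos[mol_idx],
                      n_damage = molecules$n_damage[mol_idx],
                      n_error = n_err,
                      origin = molecules$origin[mol_idx],
                      stringsAsFactors = FALSE)
  list(r1 = data.frame(id = ids, seq = r1_seq, qual = rep(qual, n_reads),
                       stringsAsFactors = FALSE),
       r2 = data.frame(id = ids, seq = r2_seq, qual = rep(qual, n_reads),
                       stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a complete sample (molecules + amplification + sequencing)
#'
#' Convenience wrapper chaining [simulate_molecules()] and [amplify_and_sequence()].
#'
#' @inheritParams simulate_molecules
#' @return As [amplify_and_sequence()], plus `molecules`.
#' @export
simulate_sample <- function(ref, panel, dmg, cfg, lin = NULL, contaminant_ref = NULL) {
  mols <- simulate_molecules(ref, panel, dmg, cfg, lin = lin,
                             contaminant_ref = contaminant_ref)
  out <- amplify_and_sequence(mols, cfg)
  out$molecules <- mols
  out
}

#' Simulate a set of already-aligned single-end reads
#'
#' Draws `n` reads of fixed length at uniform random positions on a linearized
#' reference, on random strands, optionally applies the deamination model (both read
#' ends are treated as genuine molecule ends) and uniform sequencing error, and returns
#' them as an alignment table ready for damage scoring. Used for damage-score studies
#' where library structure is irrelevant.
#'
#' @param lin A `linearized_ncr`.
#' @param n Number of reads.
#' @param read_length Read length (<= reference length).
#' @param dmg A `sim_damage_model`, or `NULL` for undamaged (present-day) reads.
#' @param error_rate Per-base sequencing error probability; qualities are emitted as the
#'   matching constant Phred score.
#' @param seed Integer seed.
#' @return An alignment data frame (see [align_reads()]) with truth columns
#'   `n_damage` and `n_error`.
#' @export
simulate_read_set <- function(lin, n, read_length = 100L, dmg = NULL,
                              error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(lin, "linearized_ncr"), read_length <= lin$length)
  restore <- seed_guard(seed)
  on.exit(restore())
  starts <- sample.int(lin$length - read_length + 1L, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  q <- if (error_rate > 0) round(-10 * log10(error_rate)) else 40L
  qual <- strrep(intToUtf8(q + 33L), read_length)
  seqs <- character(n); n_dmg <- integer(n); n_err <- integer(n)
  for (i in seq_len(n)) {
    s <- substr(lin$sequence, starts[i], starts[i] + read_length - 1L)
    if (strand[i] == "-") s <- revcomp(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (!is.null(dmg)) {
      d <- apply_deamination(chars, dmg)
      chars <- d$chars
      n_dmg[i] <- length(d$pos)
    }
    chars2 <- apply_seq_error(chars, error_rate)
    n_err[i] <- sum(chars2 != chars)
    seqs[i] <- paste(chars2, collapse = "")
  }
  data.frame(read_id = sprintf("sim%07d", seq_len(n)),
             start = starts, end = starts + read_length - 1L,
             strand = strand, seq = seqs, qual = rep(qual, n),
             score = NA_integer_, mapq = 60L, n_mismatch = NA_integer_,
             end_mode = "both", n_damage = n_dmg, n_error = n_err,
             stringsAsFactors = FALSE)
}

#' Write a read set as 4-line FASTQ
#'
#' @param reads Read-set data frame (`id`, `seq`, `qual`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a 4-line FASTQ file into a read set
#'
#' @param path FASTQ path (gzip accepted).
#' @return Read-set data frame (`id`, `seq`, `qual`).
#' @export
read_fastq <- function(path) {
  # the mcols-dropped warning from the underlying FASTQ reader is irrelevant here
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  if (length(ss) == 0L) return(empty_reads())
  out <- data.frame(id = sub("\\s.*$", "", names(ss)),
                    seq = unname(as.character(ss)),
                    qual = unname(as.character(Biostrings::quality(ss))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a simulation truth table as TSV
#'
#' @param truth Truth data frame from [amplify_and_sequence()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
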