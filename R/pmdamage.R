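# Per-read post-mortem damage (PMD) scoring, authentication and amplicon profiling.
#
# The PMD score of a read is a log-likelihood ratio contrasting a deamination-damage
# model against a sequencing-error-only null. At every aligned position whose
# reference base is C the observation is evaluated under a C->T damage probability
# D(z) = p_background + p_max * lambda^z decaying with the 0-based distance z from the
# read's 5' end; reference-G positions mirror this from the 3' end. With base error
# probability e = 10^(-Q/10):
#   P_damage(T|C) = D(z)(1-e) + (1-D(z)) e/3     P_null(T|C) = e/3
#   P_damage(C|C) = (1-D(z))(1-e) + D(z) e/3     P_null(C|C) = 1-e
# and the score is the natural-log sum of the per-position ratios; positions whose
# reference base is A/T, or whose observed base is neither the reference base nor the
# deamination product, contribute 0. Undamaged high-quality reads therefore drift
# slightly negative, while genuine terminal deamination contributes large positive
# terms.

#' Damage model for PMD scoring
#'
#' Defaults (`p_max` 0.3, `lambda` 0.3, `p_background` 0.01) are calibrated so that
#' undamaged Q30 reads rarely reach a score of 1 while deaminated reads usually do.
#'
#' @param p_max Terminal damage magnitude.
#' @param lambda Geometric decay per base in (0, 1).
#' @param p_background Position-independent damage probability.
#' @return An object of class `damage_model`.
#' @export
damage_model <- function(p_max = 0.3, lambda = 0.3, p_background = 0.01) {
  stopifnot(p_max >= 0, lambda > 0, lambda < 1, p_background >= 0,
            p_max + p_background < 1)
  structure(list(p_max = p_max, lambda = lambda, p_background = p_background),
            class = "damage_model")
}

# Score one read given oriented reference/observed base vectors and qualities.
# mode: "both" (merged: both ends genuine), "five" (only the 5' end genuine),
# "three" (only the 3' end genuine). Non-genuine ends fall back to background-only
# damage, since the molecule end lies beyond the read.
pmd_score_one <- function(ref_chars, obs_chars, quals, model, mode = "both") {
  n <- length(ref_chars)
  if (n == 0L) return(0)
  eps <- 10^(-quals / 10)
  z5 <- seq_len(n) - 1
  z3 <- n - seq_len(n)
  d_c <- if (mode %in% c("both", "five"))
    model$p_background + model$p_max * model$lambda^z5
  else rep(model$p_background, n)
  d_g <- if (mode %in% c("both", "three"))
    model$p_background + model$p_max * model$lambda^z3
  else rep(model$p_background, n)
  total <- 0
  is_c <- ref_chars == "C"
  is_g <- ref_chars == "G"
  # C sites
  hit <- is_c & obs_chars == "T"
  match <- is_c & obs_chars == "C"
  total <- total +
    sum(log((d_c[hit] * (1 - eps[hit]) + (1 - d_c[hit]) * eps[hit] / 3) /
              (eps[hit] / 3))) +
    sum(log(((1 - d_c[match]) * (1 - eps[match]) + d_c[match] * eps[match] / 3) /
              (1 - eps[match])))
  # G sites (3' mirrored)
  hit <- is_g & obs_chars == "A"
  match <- is_g & obs_chars == "G"
  total <- total +
    sum(log((d_g[hit] * (1 - eps[hit]) + (1 - d_g[hit]) * eps[hit] / 3) /
              (eps[hit] / 3))) +
    sum(log(((1 - d_g[match]) * (1 - eps[match]) + d_g[match] * eps[match] / 3) /
              (1 - eps[match])))
  total
}

#' PMD score of aligned reads
#'
#' Scores are computed in sequenced orientation: reverse-strand alignments are
#' evaluated against the reverse-complemented reference window, so the 5' end of the
#' score model is always the sequenced 5' end. The per-alignment `end_mode` column
#' ("both"/"five"/"three") controls which read ends are treated as genuine molecule
#' ends; the other end's sites use background-only damage.
#'
#' @param aln Alignment data frame.
#' @param lin The `linearized_ncr` the alignments refer to.
#' @param model A `damage_model`.
#' @return Numeric vector of PMD scores, one per alignment.
#' @export
pmd_score <- function(aln, lin, model = damage_model()) {
  aln <- check_alignments(aln)
  stopifnot(inherits(lin, "linearized_ncr"), inherits(model, "damage_model"))
  n <- nrow(aln)
  if (n == 0L) return(numeric(0))
  refc <- strsplit(lin$sequence, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  obs_all <- strsplit(aln$seq, "", fixed = TRUE)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    rc <- refc[aln$start[i]:aln$end[i]]
    if (aln$strand[i] == "-") rc <- unname(comp[rev(rc)])
    q <- aln$qual[i]
    if (is.na(q) || nchar(q) == 0L) {
      warning("missing qualities; assuming Q30")
      quals <- rep(30L, nchar(aln$seq[i]))
    } else {
      quals <- qual_to_int(q)
    }
    scores[i] <- pmd_score_one(rc, obs_all[[i]], quals, model, aln$end_mode[i])
  }
  scores
}

#' Extract damaged reads at a PMD-score threshold
#'
#' @param aln Alignment data frame.
#' @param lin The `linearized_ncr`.
#' @param model A `damage_model`.
#' @param threshold Score threshold; reads with score >= threshold (inclusive) are
#'   classified as damaged. Default 1.
#' @return A list with `damaged` (alignment subset), `scores` (all scores) and `stats`
#'   (fields `n_aligned`, `n_damaged`, `pct_damaged`, `threshold`, and `empty` flag).
#' @export
extract_damaged <- function(aln, lin, model = damage_model(), threshold = 1) {
  aln <- check_alignments(aln)
  scores <- pmd_score(aln, lin, model)
  keep <- scores >= threshold
  damaged <- aln[keep, , drop = FALSE]
  rownames(damaged) <- NULL
  n <- nrow(aln)
  stats <- list(n_aligned = n, n_damaged = sum(keep),
                pct_damaged = if (n > 0L) 100 * sum(keep) / n else 0,
                threshold = threshold, empty = n == 0L)
  list(damaged = damaged, scores = scores, stats = stats)
}

#' Authenticate a sample from its damage percentage and NCR recovery
#'
#' At the working threshold (PMD score 1), a sample with at least 80% of the NCR
#' recovered is consistent with ancient DNA when more than 9.17% of its useful reads
#' are damaged; at or below that value, present-day contamination cannot be excluded.
#' Below 80% recovery the damage percentage is likely underestimated and no verdict is
#' issued.
#'
#' @param stats Damage statistics (list with `pct_damaged`), as from
#'   [extract_damaged()] at threshold 1.
#' @param ncr_recovery_pct Percentage of the panel span recovered at the minimum depth
#'   (see [ncr_recovery()]).
#' @param pct_threshold Damage-percentage threshold (default 9.17).
#' @param recovery_threshold Minimum recovery percentage (default 80).
#' @return One of `"consistent-with-ancient"`, `"caution-possible-contamination"`,
#'   `"insufficient-recovery"`.
#' @export
authenticate_sample <- function(stats, ncr_recovery_pct, pct_threshold = 9.17,
                                recovery_threshold = 80) {
  if (ncr_recovery_pct < recovery_threshold) return("insufficient-recovery")
  if (stats$pct_damaged > pct_threshold) "consistent-with-ancient"
  else "caution-possible-contamination"
}

#' NCR recovery percentage
#'
#' Percentage of positions in the panel span whose depth reaches `min_depth`.
#'
#' @param pileup A pileup (see [build_pileup()]).
#' @param panel An `amplicon_panel`.
#' @param min_depth Minimum depth (default 10).
#' @return Percentage in \[0, 100\].
#' @export
ncr_recovery <- function(pileup, panel, min_depth = 10L) {
  span <- attr(panel, "span")
  depth <- pileup$depth[span[1]:span[2]]
  100 * sum(depth >= min_depth) / (span[2] - span[1] + 1L)
}

#' Per-amplicon depth and damage profile
#'
#' Assigns deduplicated alignments to amplicons by maximal insert overlap, counts
#' unique reads per amplicon (depth coverage), computes the percentage of damaged
#' reads per amplicon, and reports the Spearman rank correlation (average-rank ties)
#' between the two columns. Amplicons with no assigned reads get `NA` percentages and
#' are excluded from the correlation.
#'
#' @param all_aln Deduplicated alignment data frame (all useful reads).
#' @param damaged_aln Subset of `all_aln` classified as damaged.
#' @param panel An `amplicon_panel`.
#' @return A list with `profile` (data frame: `amplicon`, `depth`, `n_damaged`,
#'   `pct_damaged`) and `rho` (Spearman correlation of depth vs damage percentage).
#' @export
amplicon_profile <- function(all_aln, damaged_aln, panel) {
  all_aln <- check_alignments(all_aln)
  damaged_aln <- check_alignments(damaged_aln)
  amp_all <- assign_amplicon(panel, all_aln$start, all_aln$end)
  amp_dmg <- assign_amplicon(panel, damaged_aln$start, damaged_aln$end)
  idx <- sort(panel$index)
  depth <- vapply(idx, function(a) sum(amp_all == a, na.rm = TRUE), integer(1))
  n_dmg <- vapply(idx, function(a) sum(amp_dmg == a, na.rm = TRUE), integer(1))
  pct <- ifelse(depth > 0L, 100 * n_dmg / depth, NA_real_)
  ok <- !is.na(pct)
  rho <- if (sum(ok) >= 3L && stats::sd(depth[ok]) > 0 && stats::sd(pct[ok]) > 0)
    stats::cor(depth[ok], pct[ok], method = "spearman")
  else NA_real_
  list(profile = data.frame(amplicon = idx, depth = depth, n_damaged = n_dmg,
                            pct_damaged = pct),
       rho = rho)
}

#' Damage-percentage sweep across PMD-score thresholds
#'
#' @param aln Alignment data frame.
#' @param lin The `linearized_ncr`.
#' @param model A `damage_model`.
#' @param thresholds Numeric vector of thresholds (default -1, 0, 1, 2, 3).
#' @return Data frame with `threshold`, `n_damaged`, `pct_damaged`.
#' @export
pmd_threshold_sweep <- function(aln, lin, model = damage_model(),
                                thresholds = c(-1, 0, 1, 2, 3)) {
  aln <- check_alignments(aln)
  scores <- pmd_score(aln, lin, model)
  n <- nrow(aln)
  data.frame(threshold = thresholds,
             n_damaged = vapply(thresholds, function(t) sum(scores >= t), integer(1)),
             pct_damaged = vapply(thresholds, function(t)
               if (n > 0L) 100 * sum(scores >= t) / n else 0, numeric(1)))
}
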