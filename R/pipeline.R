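# End-to-end orchestration: the full per-sample pipeline and the two methodological
# comparisons (deduplication engines, PMD threshold sweep).

#' Pipeline configuration
#'
#' Defaults mirror the published workflow: primer trims 25/5, minimum read length 30,
#' paired-end merge for overlaps over 10 bp, mapping quality strictly over 30, PMD
#' score threshold 1, minimum allele depth 10, frequency window 30-70%, exclusion of
#' rCRS 303-315.
#'
#' @param cut_start,cut_end Linearization cut (default 15901/700).
#' @param min_depth Minimum allele depth for calling and range reporting.
#' @param min_freq,mixed_upper Allele-frequency window.
#' @param min_mapq Strict lower bound on mapping quality.
#' @param pmds_threshold PMD-score threshold for the damaged subset.
#' @param primer_trim_5p,primer_trim_3p Primer trims (bp).
#' @param min_length Minimum read length after trimming.
#' @param min_base_quality Minimum base quality in the pileup.
#' @param min_overlap Merge overlap bound (strict).
#' @param kmer K-mer length of the aligner index.
#' @param excluded_region rCRS interval excluded from calling.
#' @param seed Seed for any simulation driven through this config.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cut_start = 15901L, cut_end = 700L, min_depth = 10L,
                            min_freq = 0.30, mixed_upper = 0.70, min_mapq = 30L,
                            pmds_threshold = 1, primer_trim_5p = 25L,
                            primer_trim_3p = 5L, min_length = 30L,
                            min_base_quality = 20L, min_overlap = 10L,
                            kmer = 13L, excluded_region = c(303L, 315L), seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a key=value pipeline configuration file
#'
#' Unknown keys are rejected; values are coerced to the type of the default.
#'
#' @param path Path to a plain-text file with one `key=value` per line (`#` comments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- pipeline_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (is.numeric(cfg[[key]]))
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]])
    else val
  }
  cfg
}

#' Run the full pipeline on one sample
#'
#' Stages: trimming, exact-sequence pair deduplication, paired-end merging, alignment
#' to the linearized NCR, mapping-quality filtering, PMD extraction, then pileup,
#' range, variant calling, haplotype and reports twice (all useful reads and the
#' damaged-only subset), plus the mixed-base report, contamination check,
#' authentication verdict and summary row.
#'
#' @param sample_id Sample identifier.
#' @param r1,r2 Read-set data frames or FASTQ paths (mates in the same order).
#' @param ref The canonical `circular_reference` (e.g. rCRS).
#' @param panel Optional `amplicon_panel`; the default PowerSeq CRM panel if `NULL`.
#' @param config A `pipeline_config`.
#' @return A list with `summary` (one-row data frame), `hsd_all`, `hsd_damaged`
#'   (HSD line or `NULL`), `calls_all`, `calls_damaged`, `mixed_report`,
#'   `contamination`, `verdict`, `useful_aln`, `damaged_aln`, `pileup_all`,
#'   `pileup_damaged`, `stage_counts` and `status` (`"ok"` or a diagnostic).
#' @export
run_sample <- function(sample_id, r1, r2, ref, panel = NULL,
                       config = pipeline_config()) {
  stopifnot(inherits(ref, "circular_reference"), inherits(config, "pipeline_config"))
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  check_reads(r1); check_reads(r2)
  stopifnot(nrow(r1) == nrow(r2))
  lin <- linearize_reference(ref, config$cut_start, config$cut_end)
  if (is.null(panel))
    panel <- default_panel(lin, config$primer_trim_5p, config$primer_trim_3p)
  n_initial <- nrow(r1) + nrow(r2)
  counts <- list(initial = n_initial)

  fail <- function(status) {
    summary <- data.frame(sample_id = sample_id, n_initial = n_initial,
                          status = status, stringsAsFactors = FALSE)
    list(summary = summary, hsd_all = NULL, hsd_damaged = NULL,
         calls_all = NULL, calls_damaged = NULL, mixed_report = NULL,
         contamination = NULL, verdict = NULL, useful_aln = NULL,
         damaged_aln = NULL, pileup_all = NULL, pileup_damaged = NULL,
         stage_counts = counts, status = status)
  }
  if (n_initial == 0L) return(fail("no input reads"))

  # 1. trimming (both mates; a pair survives only if both mates do)
  t1 <- trim_reads(r1, primer_trim_5p = config$primer_trim_5p,
                   primer_trim_3p = config$primer_trim_3p,
                   min_length = config$min_length)
  t2 <- trim_reads(r2, primer_trim_5p = config$primer_trim_5p,
                   primer_trim_3p = config$primer_trim_3p,
                   min_length = config$min_length)
  keep <- intersect(t1$id, t2$id)
  t1 <- t1[match(keep, t1$id), , drop = FALSE]
  t2 <- t2[match(keep, t2$id), , drop = FALSE]
  counts$post_trim_pairs <- length(keep)
  if (length(keep) == 0L) return(fail("no reads survived trimming"))

  # 2. exact-sequence deduplication on pairs
  dd <- dedup_exact(t1, t2)
  counts$post_dedup_pairs <- dd$stats$n_after
  dup_rate <- dd$stats$duplication_rate

  # 3. merging
  mg <- merge_pairs(dd$reads, dd$reads2, min_overlap = config$min_overlap)
  counts$merged <- nrow(mg$merged)
  counts$unmerged_pairs <- nrow(mg$unmerged$r1)

  # 4. alignment (merged reads carry both molecule ends; unmerged mates one each)
  index <- build_index(lin, config$kmer)
  alignable <- function(x) x[nchar(x$seq) >= 30L, , drop = FALSE]
  aln <- rbind(align_reads(index, alignable(mg$merged), end_mode = "both"),
               align_reads(index, alignable(mg$unmerged$r1), end_mode = "five"),
               align_reads(index, alignable(mg$unmerged$r2), end_mode = "three"))
  counts$aligned <- nrow(aln)

  # 5. mapping-quality filter -> useful reads
  useful <- mapq_filter(aln, config$min_mapq)
  counts$useful <- nrow(useful)
  if (nrow(useful) == 0L) return(fail("zero useful reads"))

  # 6. PMD extraction
  dmg <- extract_damaged(useful, lin, damage_model(), config$pmds_threshold)
  counts$damaged <- dmg$stats$n_damaged

  # 7. pileups, ranges, calls, haplotypes - all reads and damaged-only
  pu_all <- build_pileup(useful, lin, config$min_base_quality)
  cov_all <- covered_intervals(pu_all, lin, config$min_depth)
  calls_all <- call_variants(pu_all, lin, ref, config$min_depth, config$min_freq,
                             config$mixed_upper, config$excluded_region)
  tokens_all <- haplotype_tokens(calls_all)
  hsd_all <- format_hsd(sample_id, cov_all$range_string, list(tokens_all))

  pu_dmg <- build_pileup(dmg$damaged, lin, config$min_base_quality)
  cov_dmg <- covered_intervals(pu_dmg, lin, config$min_depth)
  calls_dmg <- call_variants(pu_dmg, lin, ref, config$min_depth, config$min_freq,
                             config$mixed_upper, config$excluded_region)
  tokens_dmg <- haplotype_tokens(calls_dmg)
  hsd_dmg <- if (nrow(dmg$damaged) > 0L)
    format_hsd(paste0(sample_id, "_damaged"), cov_dmg$range_string, list(tokens_dmg))
  else NULL

  # 8. reports
  mixed <- mixed_base_report(sample_id, calls_all)
  contam <- contamination_check(calls_all, calls_dmg, pu_all, pu_dmg,
                                mixed_count = nrow(mixed),
                                min_depth = config$min_depth)
  recovery <- ncr_recovery(pu_all, panel, config$min_depth)
  verdict <- authenticate_sample(dmg$stats, recovery)
  summary <- sample_summary(sample_id, n_initial, dup_rate, useful, dmg$stats,
                            pu_all, panel, nrow(mixed), cov_all$range_string,
                            tokens_all)
  summary$ncr_recovery <- recovery
  summary$verdict <- verdict
  summary$status <- "ok"

  list(summary = summary, hsd_all = hsd_all, hsd_damaged = hsd_dmg,
       calls_all = calls_all, calls_damaged = calls_dmg, mixed_report = mixed,
       contamination = contam, verdict = verdict, useful_aln = useful,
       damaged_aln = dmg$damaged, pileup_all = pu_all, pileup_damaged = pu_dmg,
       stage_counts = counts, status = "ok")
}

# Descriptive statistics row (linear-interpolation percentiles, quantile type 7).
descriptive_stats <- function(x) {
  qs <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7, names = FALSE)
  data.frame(mean = mean(x), median = qs[3L], iqr = qs[4L] - qs[2L],
             p2.5 = qs[1L], p97.5 = qs[5L], min = min(x), max = max(x))
}

#' Compare the two deduplication engines across samples
#'
#' For each sample, runs the preprocessing common to both workflows, then applies (a)
#' exact-sequence deduplication before merging/alignment and (b) coordinate-class
#' deduplication after alignment and mapping-quality filtering, recording useful-read
#' counts and duplication rates per engine, plus descriptive statistics (mean, median,
#' IQR, 2.5th/97.5th percentiles, min, max) across samples.
#'
#' @param samples Named list; each element a list with `r1`, `r2` read-set data
#'   frames (or FASTQ paths).
#' @param ref The canonical `circular_reference`.
#' @param panel Optional `amplicon_panel`.
#' @param config A `pipeline_config`.
#' @return A list with `per_sample` (data frame: sample, engine, useful reads,
#'   duplication rate) and `descriptives` (one row per engine and measure).
#' @export
dedup_compare <- function(samples, ref, panel = NULL, config = pipeline_config()) {
  stopifnot(length(samples) >= 1L)
  lin <- linearize_reference(ref, config$cut_start, config$cut_end)
  index <- build_index(lin, config$kmer)
  if (is.null(panel))
    panel <- default_panel(lin, config$primer_trim_5p, config$primer_trim_3p)
  rows <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    r1 <- if (is.character(s$r1)) read_fastq(s$r1) else s$r1
    r2 <- if (is.character(s$r2)) read_fastq(s$r2) else s$r2
    t1 <- trim_reads(r1, primer_trim_5p = config$primer_trim_5p,
                     primer_trim_3p = config$primer_trim_3p,
                     min_length = config$min_length)
    t2 <- trim_reads(r2, primer_trim_5p = config$primer_trim_5p,
                     primer_trim_3p = config$primer_trim_3p,
                     min_length = config$min_length)
    keep <- intersect(t1$id, t2$id)
    t1 <- t1[match(keep, t1$id), , drop = FALSE]
    t2 <- t2[match(keep, t2$id), , drop = FALSE]

    align_pairs <- function(p1, p2) {
      mg <- merge_pairs(p1, p2, min_overlap = config$min_overlap)
      ok <- function(x) x[nchar(x$seq) >= 30L, , drop = FALSE]
      rbind(align_reads(index, ok(mg$merged), end_mode = "both"),
            align_reads(index, ok(mg$unmerged$r1), end_mode = "five"),
            align_reads(index, ok(mg$unmerged$r2), end_mode = "three"))
    }
    # engine A: exact-sequence dedup before merging/alignment
    dd <- dedup_exact(t1, t2)
    useful_exact <- mapq_filter(align_pairs(dd$reads, dd$reads2), config$min_mapq)
    # engine B: coordinate-class dedup after alignment + mapq filter
    useful_raw <- mapq_filter(align_pairs(t1, t2), config$min_mapq)
    dc <- dedup_by_coordinates(useful_raw)
    rows[[nm]] <- data.frame(
      sample = nm,
      engine = c("exact-sequence", "coordinate-class"),
      n_useful = c(nrow(useful_exact), nrow(dc$aln)),
      duplication_rate = c(dd$stats$duplication_rate, dc$stats$duplication_rate),
      stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL
  desc <- do.call(rbind, lapply(split(per_sample, per_sample$engine), function(d) {
    cbind(data.frame(engine = d$engine[1L],
                     measure = c("n_useful", "duplication_rate")),
          rbind(descriptive_stats(d$n_useful),
                descriptive_stats(d$duplication_rate)))
  }))
  rownames(desc) <- NULL
  list(per_sample = per_sample, descriptives = desc)
}
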