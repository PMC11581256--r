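# Pileup, coverage intervals, variant/mixed-base calling, HSD emission and the
# contamination screen.


test_that("pileups count quality-passing bases in forward orientation", {
  f <- fix()
  # 10 identical error-free alignments covering [100,150]
  a <- mk_aln(rep(100L, 10), rep(150L, 10), "+", lin = f$lin)
  pu <- build_pileup(a, f$lin)
  expect_true(all(pu$depth[100:150] == 10L))
  expect_true(all(pu$depth[-(100:150)] == 0L))
  # a Q10 base is excluded from its column
  b <- mk_aln(100L, 150L, "+", lin = f$lin)
  q <- strsplit(b$qual, "")[[1]]; q[1] <- intToUtf8(10 + 33)
  b$qual <- paste(q, collapse = "")
  pu2 <- build_pileup(b, f$lin)
  expect_equal(pu2$depth[100], 0L)
  expect_equal(pu2$depth[101], 1L)
  # reverse-strand alignments contribute their forward-orientation bases
  c1 <- mk_aln(200L, 260L, "-", lin = f$lin)
  pu3 <- build_pileup(c1, f$lin)
  base_at <- rownames(pu3$counts)[which(pu3$counts[, 230] == 1L)]
  expect_identical(base_at, substr(f$lin$sequence, 230, 230))
})

test_that("pileup counts equal an independent per-column recount on simulated reads", {
  f <- fix()
  aln <- simulate_read_set(f$lin, n = 1000, read_length = 60,
                           dmg = sim_damage_model(), error_rate = 0.01, seed = 3)
  pu <- build_pileup(aln, f$lin, min_base_quality = 0L)
  # oracle: tabulate forward-oriented bases per column with nested loops
  counts <- matrix(0L, 4, f$lin$length, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(aln))) {
    s <- aln$seq[i]
    if (aln$strand[i] == "-") s <- mtamplicon_revcomp(s)
    ch <- strsplit(s, "")[[1]]
    for (k in seq_along(ch)) {
      p <- aln$start[i] + k - 1L
      counts[ch[k], p] <- counts[ch[k], p] + 1L
    }
  }
  expect_identical(unname(pu$counts), unname(counts))
})

test_that("covered intervals split at the origin and render the range string", {
  f <- fix()
  span <- attr(f$panel, "span")
  mk_pileup_depth <- function(depth_vec) {
    structure(list(counts = rbind(A = depth_vec,
                                  C = integer(f$lin$length),
                                  G = integer(f$lin$length),
                                  T = integer(f$lin$length)),
                   depth = depth_vec, length = f$lin$length), class = "pileup")
  }
  d <- integer(f$lin$length); d[span[1]:span[2]] <- 20L
  cov <- covered_intervals(mk_pileup_depth(d), f$lin)
  expect_identical(cov$range_string, "16013-16569;1-592")
  # depth below threshold everywhere -> empty
  expect_equal(nrow(covered_intervals(mk_pileup_depth(rep(5L, f$lin$length)),
                                      f$lin)$intervals), 0L)
  # one internal gap -> two intervals
  d2 <- d; d2[300:310] <- 0L
  cov2 <- covered_intervals(mk_pileup_depth(d2), f$lin)
  expect_equal(nrow(cov2$intervals), 3L)  # gap + origin split
  # monotone in min_depth: raising it never extends coverage
  cov_hi <- covered_intervals(mk_pileup_depth(d), f$lin, min_depth = 25L)
  expect_equal(nrow(cov_hi$intervals), 0L)
})

test_that("IUPAC codes follow the standard table", {
  expect_identical(iupac_code(c("C", "T")), "Y")
  expect_identical(iupac_code(c("A", "G")), "R")
  expect_identical(iupac_code(c("G", "A")), "R")
  expect_identical(iupac_code(c("A", "C", "G", "T")), "N")
  expect_identical(iupac_code(c("A", "C", "T")), "H")
  expect_identical(iupac_code("G"), "G")
  expect_error(iupac_code(character(0)), "empty")
})

# Build a pileup with chosen counts at chosen linear positions.
pileup_with <- function(lin, at, counts_list) {
  counts <- matrix(0L, 4, lin$length, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(at)) counts[names(counts_list[[j]]), at[j]] <- counts_list[[j]]
  structure(list(counts = counts, depth = colSums(counts), length = lin$length),
            class = "pileup")
}

test_that("variant calls follow the 30/70 window, depth gate and excluded region", {
  f <- fix()
  ref <- f$ref
  # choose linear positions whose reference base is C
  cpos <- which(strsplit(f$lin$sequence, "")[[1]] == "C")
  p1 <- cpos[100]; p2 <- cpos[120]
  pu <- pileup_with(f$lin, c(p1, p2),
                    list(c(T = 80L, C = 20L), c(T = 60L, C = 40L)))
  calls <- call_variants(pu, f$lin, ref)
  expect_equal(nrow(calls), 2L)
  c1 <- calls[calls$lin_pos == p1, ]
  expect_identical(c1$type, "substitution")
  expect_identical(c1$call, "T")
  expect_equal(c1$alt_pct, 80)
  c2 <- calls[calls$lin_pos == p2, ]
  expect_identical(c2$type, "mixed")
  expect_identical(c2$call, "Y")
  expect_equal(c2$alt_pct, 60)
  # depth below 10 -> no call
  pu_lo <- pileup_with(f$lin, p1, list(c(T = 6L, C = 2L)))
  expect_equal(nrow(call_variants(pu_lo, f$lin, ref)), 0L)
  # rCRS 310 is inside the excluded region: never called
  p310 <- to_linear(f$lin, 310)
  pu310 <- pileup_with(f$lin, p310, list(c(A = 50L, C = 50L)))
  expect_equal(nrow(call_variants(pu310, f$lin, ref)), 0L)
  # reference-only columns produce no call
  refb <- substr(f$lin$sequence, p1, p1)
  cnt <- stats::setNames(100L, refb)
  expect_equal(nrow(call_variants(pileup_with(f$lin, p1, list(cnt)), f$lin, ref)), 0L)
})

test_that("calls agree with a recount-and-classify oracle on simulated samples", {
  f <- fix()
  aln <- simulate_read_set(f$lin, n = 2000, read_length = 80,
                           dmg = sim_damage_model(), error_rate = 0.01, seed = 9)
  pu <- build_pileup(aln, f$lin)
  calls <- call_variants(pu, f$lin, f$ref)
  lin_chars <- strsplit(f$lin$sequence, "")[[1]]
  mismatches <- 0L; n_oracle_calls <- 0L
  for (p in seq_len(f$lin$length)) {
    rcrs <- to_circular(f$lin, p)
    if (rcrs >= 303 && rcrs <= 315) next
    want <- classify_oracle(pu$counts[, p], lin_chars[p])
    got <- calls[calls$lin_pos == p, ]
    if (is.null(want)) {
      if (nrow(got) != 0L) mismatches <- mismatches + 1L
    } else {
      n_oracle_calls <- n_oracle_calls + 1L
      if (nrow(got) != 1L || got$type != want$type || got$call != want$call)
        mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
  expect_equal(n_oracle_calls, nrow(calls))
  # no calls inside the excluded region or below depth
  expect_true(all(calls$rcrs_pos < 303 | calls$rcrs_pos > 315))
  expect_true(all(calls$depth >= 10))
})

test_that("haplotypes order tokens along the NCR traversal and round-trip as HSD", {
  f <- fix()
  cpos <- which(strsplit(f$lin$sequence, "")[[1]] == "C")
  # one token in the 16xxx arc, one after the origin
  pa <- cpos[cpos < 600][50]; pb <- cpos[cpos > 700][50]
  pu <- pileup_with(f$lin, c(pb, pa),
                    list(c(T = 60L, C = 40L), c(T = 90L, C = 10L)))
  calls <- call_variants(pu, f$lin, f$ref)
  tok <- haplotype_tokens(calls)
  expect_identical(tok, c(paste0(to_circular(f$lin, pa), "T"),
                          paste0(to_circular(f$lin, pb), "Y")))
  line <- format_hsd("S1", "16013-16569;1-592", tok)
  expect_identical(line, paste(c("S1", "16013-16569;1-592", "?", tok), collapse = "\t"))
  # empty haplotype -> three-field line
  expect_identical(format_hsd("S2", "1-10", character(0)), "S2\t1-10\t?")
  path <- withr::local_tempfile(fileext = ".hsd")
  write_hsd(c("S1", "S2"), c("16013-16569;1-592", "1-10"),
            list(tok, character(0)), path)
  back <- read_hsd(path)
  expect_identical(back$id, c("S1", "S2"))
  expect_identical(back$haplogroup, c("?", "?"))
  expect_identical(back$haplotype, c(paste(tok, collapse = " "), ""))
})

test_that("the mixed-base report carries the six fields for mixed calls only", {
  f <- fix()
  cpos <- which(strsplit(f$lin$sequence, "")[[1]] == "C")
  pu <- pileup_with(f$lin, c(cpos[10], cpos[30]),
                    list(c(T = 60L, C = 40L), c(T = 90L, C = 10L)))
  calls <- call_variants(pu, f$lin, f$ref)
  rep1 <- mixed_base_report("S1", calls)
  expect_equal(nrow(rep1), 1L)
  expect_identical(names(rep1),
                   c("sample_id", "position", "alt_base", "depth", "alt_count", "alt_pct"))
  expect_equal(rep1$alt_pct, 60)
  expect_true(all(rep1$alt_pct >= 30 & rep1$alt_pct <= 70))
  # substitution-only sample -> empty report
  pu2 <- pileup_with(f$lin, cpos[30], list(c(T = 90L, C = 10L)))
  expect_equal(nrow(mixed_base_report("S1", call_variants(pu2, f$lin, f$ref))), 0L)
})

test_that("planted haplotypes are recovered exactly at 50x error-free coverage", {
  f <- fix()
  for (k in c(0L, 1L, 5L)) {
    toks <- character(0)
    if (k > 0) {
      positions <- c(16126L, 73L, 16224L, 263L, 489L)[seq_len(k)]
      toks <- vapply(positions, function(p) alt_token(f$ref, p), character(1))
    }
    sample_ref <- plant_haplotype(f$ref, toks)
    sample_lin <- linearize_reference(sample_ref)
    aln <- simulate_read_set(sample_lin, n = 1200, read_length = 60, dmg = NULL,
                             error_rate = 0, seed = 100L + k)
    pu <- build_pileup(aln, f$lin)
    calls <- call_variants(pu, f$lin, f$ref)
    got <- haplotype_tokens(calls)
    want <- toks[order(to_linear(f$lin, parse_token_pos(toks)))]
    expect_identical(got, want)
  }
})

test_that("contamination is flagged on discordance or multiple mixed bases", {
  f <- fix()
  cpos <- which(strsplit(f$lin$sequence, "")[[1]] == "C")
  p <- cpos[200]
  pu_all <- pileup_with(f$lin, p, list(c(T = 12L, C = 8L)))        # mixed 60%
  pu_dmg <- pileup_with(f$lin, p, list(c(T = 11L, C = 1L)))        # damaged: T
  calls_all <- call_variants(pu_all, f$lin, f$ref)
  calls_dmg <- call_variants(pu_dmg, f$lin, f$ref)
  chk <- contamination_check(calls_all, calls_dmg, pu_all, pu_dmg, mixed_count = 1)
  expect_identical(chk$flag, "possible contamination")
  expect_equal(chk$n_discordant, 1L)
  # identical profiles, no mixed bases -> clean
  chk2 <- contamination_check(calls_dmg, calls_dmg, pu_dmg, pu_dmg, mixed_count = 0)
  expect_identical(chk2$flag, "no contamination detected")
  # concordant haplotypes but two mixed bases -> flagged
  chk3 <- contamination_check(calls_dmg, calls_dmg, pu_dmg, pu_dmg, mixed_count = 2)
  expect_identical(chk3$flag, "possible contamination")
  # empty damaged profile -> not evaluable
  pu0 <- pileup_with(f$lin, p, list(c(T = 0L, C = 0L)))
  chk4 <- contamination_check(calls_all, calls_all[0, ], pu_all, pu0, mixed_count = 0)
  expect_identical(chk4$flag, "not evaluable")
})

test_that("sample summaries report the documented fields", {
  f <- fix()
  aln <- simulate_read_set(f$lin, n = 1500, read_length = 100, dmg = NULL,
                           error_rate = 0, seed = 77)
  pu <- build_pileup(aln, f$lin)
  st <- list(n_damaged = 10L, pct_damaged = 100 * 10 / 1500)
  s <- sample_summary("S1", 3000L, 0.25, aln, st, pu, f$panel, 0L,
                      "16013-16569;1-592", character(0))
  expect_identical(s$haplogroup, "?")
  expect_equal(s$pct_useful, 100 * 1500 / 3000)
  # uniform-ish random placement at ~1500*100/1369 per-position expectation
  expect_lt(abs(s$mean_depth - 1500 * 100 / 1369) / (1500 * 100 / 1369), 0.10)
})
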