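# PMD log-likelihood scoring, extraction, authentication and amplicon profiling.


test_that("hand-checked two-base example and degenerate cases score correctly", {
  f <- fix()
  model <- damage_model()
  # locate a reference "CA" dinucleotide and observe "TA": single 5'-terminal C->T
  pos <- regexpr("CA", f$lin$sequence)[1]
  aln <- mk_aln(pos, pos + 1L, "+", seq = "TA", q = 30L)
  s <- pmd_score(aln, f$lin, model)
  # ln(P_damage(T|C)/P_null(T|C)) at z=0: D=0.31, e=0.001
  expected <- log((0.31 * 0.999 + 0.69 * 0.001 / 3) / (0.001 / 3))
  expect_equal(s, expected, tolerance = 1e-12)
  expect_equal(round(s, 2), 6.83)
  # no reference C or G -> empty sum
  pos_at <- regexpr("AT", f$lin$sequence)[1]
  aln_at <- mk_aln(pos_at, pos_at + 1L, "+", seq = substr(f$lin$sequence, pos_at, pos_at + 1L))
  expect_equal(pmd_score(aln_at, f$lin, model), 0)
  # perfect-match reads drift negative
  aln_pm <- mk_aln(200L, 280L, "+", lin = f$lin)
  expect_lt(pmd_score(aln_pm, f$lin, model), 0)
})

test_that("vectorized scores match the brute-force oracle to 1e-9", {
  f <- fix()
  model <- damage_model()
  aln <- simulate_read_set(f$lin, n = 400, read_length = 80,
                           dmg = sim_damage_model(), error_rate = 0.005, seed = 7)
  aln$end_mode <- rep(c("both", "five", "three"), length.out = nrow(aln))
  got <- pmd_score(aln, f$lin, model)
  want <- vapply(seq_len(nrow(aln)), function(i) {
    ref_sub <- substr(f$lin$sequence, aln$start[i], aln$end[i])
    if (aln$strand[i] == "-") ref_sub <- mtamplicon_revcomp(ref_sub)
    pmd_oracle(ref_sub, aln$seq[i], utf8ToInt(aln$qual[i]) - 33, model,
               aln$end_mode[i])
  }, numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("damaged-read extraction is monotone in the threshold", {
  f <- fix()
  aln <- simulate_read_set(f$lin, n = 300, dmg = sim_damage_model(), seed = 11)
  sets <- lapply(c(-1, 0, 1, 2, 3), function(t)
    extract_damaged(aln, f$lin, threshold = t)$damaged$read_id)
  for (j in 2:5) expect_true(all(sets[[j]] %in% sets[[j - 1]]))
  # threshold -Inf retains everything
  expect_equal(nrow(extract_damaged(aln, f$lin, threshold = -Inf)$damaged), nrow(aln))
  # empty input flagged
  st <- extract_damaged(aln[0, ], f$lin)$stats
  expect_true(st$empty)
  expect_equal(st$pct_damaged, 0)
})

test_that("present-day samples rarely reach score 1, matching a binomial oracle", {
  f <- fix()
  aln <- simulate_read_set(f$lin, n = 10000, read_length = 100, dmg = NULL,
                           error_rate = 0.001, seed = 13)
  st <- extract_damaged(aln, f$lin, threshold = 1)$stats
  # oracle: a read is flagged (essentially) iff >= 1 C->T or G->A sequencing error;
  # each C/G site converts with probability error/3
  n_cg <- vapply(seq_len(nrow(aln)), function(i) {
    ref_sub <- substr(f$lin$sequence, aln$start[i], aln$end[i])
    if (aln$strand[i] == "-") ref_sub <- mtamplicon_revcomp(ref_sub)
    sum(strsplit(ref_sub, "")[[1]] %in% c("C", "G"))
  }, numeric(1))
  pred <- mean(1 - (1 - 0.001 / 3)^n_cg)
  se <- sqrt(pred * (1 - pred) / nrow(aln))
  expect_lt(abs(st$pct_damaged / 100 - pred), 3 * se)
})

test_that("authentication applies the damage and recovery rules", {
  st <- function(pct) list(pct_damaged = pct)
  expect_identical(authenticate_sample(st(25.86), 95), "consistent-with-ancient")
  expect_identical(authenticate_sample(st(5.0), 95), "caution-possible-contamination")
  expect_identical(authenticate_sample(st(9.17), 95), "caution-possible-contamination")
  expect_identical(authenticate_sample(st(30), 50), "insufficient-recovery")
})

test_that("amplicon profiles match binomial oracles and flag damage concentration", {
  f <- fix()
  # profile counts equal an independent recount over assignments and scores
  dmg <- sim_damage_model()
  cfg <- sim_config(molecules_per_amplicon = rep(150L, 10), duplication_mean = 0,
                    error_rate = 0, seed = 21L)
  mols <- simulate_molecules(f$ref, f$panel, dmg, cfg)
  aln <- mk_aln(mols$lin_start, mols$lin_end, mols$strand, seq = mols$seq)
  ext <- extract_damaged(aln, f$lin, threshold = 1)
  prof <- amplicon_profile(aln, ext$damaged, f$panel)
  scores <- pmd_score(aln, f$lin, damage_model())
  amp <- assign_amplicon(f$panel, aln$start, aln$end)
  for (j in seq_len(10)) {
    expect_equal(prof$profile$depth[j], sum(amp == j))
    expect_equal(prof$profile$n_damaged[j], sum(scores[amp == j] >= 1))
  }
  # binomial oracle: two independent cohorts of the same amplicon share a flag
  # probability; their observed percentages agree within sampling error
  one_amp <- function(seed) {
    cfg1 <- sim_config(molecules_per_amplicon = c(400L, rep(0L, 9)),
                       duplication_mean = 0, error_rate = 0, seed = seed)
    m <- simulate_molecules(f$ref, f$panel, dmg, cfg1)
    a <- mk_aln(m$lin_start, m$lin_end, m$strand, seq = m$seq)
    e <- extract_damaged(a, f$lin, threshold = 1)$stats
    e$pct_damaged / 100
  }
  p1 <- one_amp(101L); p2 <- one_amp(202L)
  pbar <- (p1 + p2) / 2
  se2 <- sqrt(2 * pbar * (1 - pbar) / 400)
  expect_lt(abs(p1 - p2), 3 * se2)
  # damage concentrated on the scarcest amplicon drives a negative correlation
  few <- mk_aln(rep(f$panel$lin_start[1], 30), rep(f$panel$lin_end[1], 30), "+",
                lin = f$lin)
  many <- do.call(rbind, lapply(2:10, function(a)
    mk_aln(rep(f$panel$lin_start[a], 100), rep(f$panel$lin_end[a], 100), "+",
           lin = f$lin, ids = sprintf("m%d_%03d", a, 1:100))))
  all_aln <- rbind(few, many)
  dmg_aln <- few[1:20, ]  # only amplicon 1 carries damage
  prof2 <- amplicon_profile(all_aln, dmg_aln, f$panel)
  expect_equal(which.max(prof2$profile$pct_damaged), 1L)
  expect_lt(prof2$rho, 0)
  # perfectly anti-monotone (depth, pct) pairs give rho = -1
  all3 <- do.call(rbind, lapply(1:10, function(a) {
    n <- 110L - 10L * a
    mk_aln(rep(f$panel$lin_start[a], n), rep(f$panel$lin_end[a], n), "+",
           lin = f$lin, ids = sprintf("x%d_%03d", a, seq_len(n)))
  }))
  dmg3 <- do.call(rbind, lapply(1:10, function(a) {
    d <- all3[all3$start == f$panel$lin_start[a], , drop = FALSE]
    d[seq_len(a), , drop = FALSE]  # damage count a -> pct strictly increasing
  }))
  prof3 <- amplicon_profile(all3, dmg3, f$panel)
  expect_true(all(diff(prof3$profile$depth) < 0))
  expect_true(all(diff(prof3$profile$pct_damaged) > 0))
  expect_equal(prof3$rho, -1)
})

test_that("the threshold sweep percentage is non-increasing", {
  f <- fix()
  aln <- simulate_read_set(f$lin, n = 500, dmg = sim_damage_model(), seed = 23)
  sw <- pmd_threshold_sweep(aln, f$lin)
  expect_true(all(diff(sw$pct_damaged) <= 0))
})
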