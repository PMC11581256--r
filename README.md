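# mtamplicon

Analysis of amplicon-based next-generation sequencing data of the human
mitochondrial DNA non-coding region (NCR, the control region) from ancient and
other degraded samples: forensic and archaeological material sequenced with
panels such as the PowerSeq CRM Nested kit (10 overlapping amplicons spanning
rCRS 16013–592).

Degraded-sample amplicon data combines two difficulties that general pipelines
handle poorly. First, every read of an amplicon shares the amplicon's start and
end coordinates, so coordinate-based duplicate removal (the Picard/samtools
convention) collapses distinct template molecules into a single read;
deduplication must instead be done on exact sequence identity. Second, ancient
templates carry post-mortem deamination — C→T misincorporations at 5' ends and
complementary G→A at 3' ends — which is both a nuisance for variant calling and
the key authentication signal. `mtamplicon` implements the full workflow
natively:

- **Circular-reference linearization.** The mtDNA circle is cut at rCRS 15901
  and renumbered so the whole NCR (15901–16569;1–700, 1369 bp) is one linear
  sequence; a bijective coordinate map converts between linear and rCRS
  numbering.
- **Read preprocessing.** Adapter, poly-X, fixed 25/5 bp primer and 3' quality
  (Q20) trimming; a 30 bp length filter; paired-end merging for overlaps over
  10 bp. Both deduplication engines are provided: exact-sequence and
  coordinate-class.
- **Alignment.** A k-mer seed-and-extend ungapped aligner for the 1.4 kb
  reference with SAM read/write; reads with mapping quality over 30 are the
  "useful reads".
- **PMD scoring.** A per-read log-likelihood ratio contrasting a deamination
  model D(z) = p_bg + p_max·λ^z (defaults 0.01 + 0.3·0.3^z, decaying with the
  distance z from the read end) against a sequencing-error-only null:
  at a reference-C position, P(T|C) = D(z)(1−ε) + (1−D(z))ε/3 under damage vs
  ε/3 under the null (G→A mirrored at 3' ends). Reads with score ≥ 1 form the
  damaged subset; a sample with ≥ 80% NCR recovery and > 9.17% damaged reads is
  consistent with ancient DNA.
- **Variant calling.** Quality-filtered pileups; sites at depth ≥ 10 outside
  the rCRS 303–315 poly-C tract; alleles at ≥ 30% frequency are observed, a
  single non-reference allele above 70% is a substitution, two or more alleles
  in the 30–70% window are a mixed base reported as an IUPAC symbol. Haplotypes
  are emitted as Haplogrep-compatible HSD records (haplogroup left as `?`).
- **Contamination screening.** The haplotype of the damaged-only reads (almost
  purely endogenous) is compared with the all-reads haplotype; discordant sites
  or more than one mixed base raise a flag.
- **A seeded simulator** of degraded amplicon libraries — planted haplotypes,
  terminal deamination applied per template molecule (so PCR duplicates inherit
  it), geometric PCR duplication, quality-dependent sequencing error, adapter
  read-through and optional two-profile contamination mixtures — with a truth
  table for every read, so every stage is testable without external data.

## Worked example

```r
library(mtamplicon)

# A synthetic reference stands in for the rCRS here; for real data use
# read_reference_fasta("rCRS.fa").
ref   <- synthetic_circular_reference(seed = 7)
lin   <- linearize_reference(ref)          # rCRS 15901 -> linear position 1
panel <- default_panel(lin)                # the 10 published amplicons

# Simulate an ancient sample carrying two variants
sample_ref <- plant_haplotype(ref, c("16126C", "73A"))   # tokens vs this reference
cfg <- sim_config(molecules_per_amplicon = rep(40, 10), duplication_mean = 3,
                  error_rate = 0.001, seed = 11)
sim <- simulate_sample(sample_ref, panel, sim_damage_model(), cfg)

res <- run_sample("S1", sim$r1, sim$r2, ref)
res$summary
res$hsd_all
```

This prints:

```
  sample_id n_initial duplication_rate n_useful pct_useful mean_depth mean_mapq
1        S1      3180        0.7056604      466   14.65409   45.75022        60
  n_damaged pct_damaged n_mixed haplogroup
1       308    66.09442       0          ?
                                                      range  haplotype
1 16018-16220;16248-16383;16392-16569;1-130;141-431;448-573 16126C 73A
  ncr_recovery                 verdict status
1     92.60226 consistent-with-ancient     ok

[1] "S1\t16018-16220;16248-16383;16392-16569;1-130;141-431;448-573\t?\t16126C\t73A"
```

i.e. 3,180 raw reads collapse to 466 useful reads (70.6% amplicon duplication),
66.1% of them carry post-mortem damage at PMD score ≥ 1, 92.6% of the NCR is
recovered at depth ≥ 10 — so the sample authenticates as ancient — and both
planted variants are recovered in the HSD haplotype line with the haplogroup
field left to an external classifier.

A command-line wrapper with `simulate`, `run`, `dedup-compare`, `damage` and
`profile` subcommands is installed at `inst/cli/mtamplicon.R`.

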