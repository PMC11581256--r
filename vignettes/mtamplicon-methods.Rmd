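---
title: "Models and methods behind mtamplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtamplicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtamplicon` analyses amplicon-based NGS data of the human mtDNA non-coding
region (NCR) from degraded samples. This vignette describes the models the
package implements, the parameters that matter and their defaults, what the
simulator does and does not emulate, and the numerical and design choices made
where the design was genuinely open. It states no empirical results beyond
what the package's own tests and acceptance script compute.

## Coordinate model

mtDNA is circular; reads crossing the replication origin (rCRS 16569/1) break
against a naively linear reference. The package cuts the circle at position
15901 and renumbers so that rCRS 15901 becomes linear position 1 and rCRS 700
becomes linear position 1369. The map between the circular window
{15901..16569} ∪ {1..700} and linear {1..1369} is a bijection; `map_position()`
applies it in both directions and rejects positions outside the window
(701..15900) rather than guessing. All user-facing coordinates are 1-based
closed intervals; variant and range outputs are always reported back in rCRS
numbering, split at the origin (e.g. `16013-16569;1-592`).

The default amplicon panel is the ten published PowerSeq CRM Nested intervals
(16013–16126 … 429–592, with amplicon 5 wrapping the origin as 16474–30). The
wrapped interval is interpreted as coordinates like the others, which is the
only reading consistent with the panel tiling the 16013–592 span. Primer
sequences for the kit are proprietary, so primer-trimmed inserts are derived
from fixed end trims — 25 bp at the 5' end and 5 bp at the 3' end of each read
in molecule orientation — the same convention the trimming stage applies.
Reads are assigned to amplicons by maximal overlap with these inserts, ties
broken toward the lower amplicon index.

## Preprocessing

Trimming is a single composite pass applying, in a fixed order: 3' adapter
removal (suffix match against adapter prefixes, 1 mismatch tolerated per 8
matched bases, minimum 4 matched bases, default Illumina TruSeq sequences);
poly-X tail removal (trailing single-base run of ≥ 10 bp — the run length is a
package choice, as tools differ); the fixed 25/5 primer trims; removal of
trailing bases below Q20; and a 30 bp minimum-length filter. The original
workflow runs three successive trimming passes with the same cumulative
effect; one composite pass gives an equivalent, simpler contract.

Paired-end merging reverse-complements the second mate and searches ungapped
overlaps. Overlaps must be strictly greater than 10 bp; candidate offsets are
proposed by exact 12-mer probes plus an exhaustive scan of short suffix/prefix
overlaps, and the best-scoring offset (matches minus twice mismatches) is
accepted if its mismatch fraction is at most 20% — the tolerance is a package
choice, as the original workflow does not state one. Disagreements take the
higher-quality base; the consensus quality is the maximum of the two, so a
merged base is never reported less confident than its better observation.

Two deduplication engines are provided because they behave oppositely on
amplicon data. Exact-sequence deduplication keys on the sequence text alone
(for pairs, the ordered concatenation of both mates — qualities excluded), so
template molecules that differ anywhere survive. Coordinate-class
deduplication keys on (start, end, strand); since every molecule of an
amplicon shares the amplicon's coordinates, this collapses each amplicon to at
most two retained reads (one per strand) regardless of true library
complexity. In both engines the retained representative is the member with the
highest total base quality, ties to the first seen; the duplication rate is
1 − after/before.

## Alignment and mapping quality

At 1.4 kb reference scale, a k-mer hash (default k = 13, both strands) with
ungapped extension (+1 match / −1 mismatch) places reads exactly; gapped
alignment would add nothing because the variant caller excludes indels
entirely. A read is reported when its best score reaches 80% of its length.
The mapping quality is a deliberate simple proxy, `min(60, 4·(best −
second_best))` with `second_best = 0` for a unique placement, so tied
placements get 0 and the pipeline's strict "mapping quality over 30" filter
keeps only confidently unique placements. Reads that merged are aligned as
single fragments; mates that failed to merge are aligned independently and
each must pass the filter on its own.

## Post-mortem damage score

Deamination in degraded DNA is read as C→T changes concentrated at 5' ends
and complementary G→A changes at 3' ends. The per-read score is a
log-likelihood ratio contrasting a damage model against a sequencing-error
null. With base error probability ε = 10^(−Q/10) and damage probability
D(z) = p_bg + p_max·λ^z at 0-based distance z from the relevant read end:

- reference C, observed T: ln[(D(z)(1−ε) + (1−D(z))ε/3) / (ε/3)]
- reference C, observed C: ln[((1−D(z))(1−ε) + D(z)ε/3) / (1−ε)]
- G positions mirrored from the 3' end; all other positions contribute 0.

Natural logarithms; reverse-strand alignments are evaluated in sequenced
orientation so z always counts from the sequenced ends. The defaults
(p_max = 0.3, λ = 0.3, p_bg = 0.01) are the package's calibration: undamaged
Q30 reads score slightly negative unless a C→T/G→A sequencing error occurs
(each match contributes ≈ ln(1−D(z)), so ≈ −0.5 to −1 per 100-mer), while a
single deamination contributes ≈ +3.4 (interior) to +6.8 (terminal), putting
genuinely deaminated reads above the working threshold of 1. The threshold is
inclusive (score ≥ 1).

Merged reads carry both genuine molecule ends, so both decay models apply.
Unmerged mates carry only one: the first mate applies the 5' decay to C sites
and background-only damage to G sites, the second mate the mirror image. A
known modelling caveat: amplicons need not extend to the template's physical
ends, so some damage appears mid-read; the end-anchored decay is retained (as
in established damage-scoring practice) with p_bg capturing interior damage.
A uniform model is available by setting p_max = 0.

Authentication follows the published decision rule: with at least 80% of the
panel span recovered at depth ≥ 10, a sample whose damaged-read percentage at
threshold 1 exceeds 9.17% is consistent with ancient DNA; at or below it,
caution (possible present-day contamination); below 80% recovery no verdict is
issued because the damage percentage is likely underestimated. The panel-span
denominator is 1149 positions for the default 16013–592 span.

## Variant and mixed-base calling

Pileups count A/C/G/T per linear position from deduplicated, mapq-filtered
alignments, excluding bases below Q20. Sites qualify at quality-filtered depth
≥ 10 — frequencies are computed over counted bases, matching the Q20 handling
upstream — and outside rCRS 303–315, the poly-C tract excluded for alignment
complexity (its length heteroplasmy defeats automated interpretation; it can
be inspected manually). Alleles at frequency ≥ 0.30 are observed. A single
non-reference allele strictly above 0.70 is a substitution; two or more
observed alleles each within [0.30, 0.70] are a mixed base, written as the
IUPAC symbol over the observed alleles (a triallelic site yields a three-base
symbol and counts as one mixed base). The window boundaries are inclusive on
both sides of the mixed range — the source workflow states the 30–70% window
without boundary semantics, so the package fixes them and documents it here.

Haplotypes are token lists (`16126C`, `152Y`) ordered along the NCR traversal
16013→16569→1→592, emitted as tab-separated HSD records with `?` for the
haplogroup (classification is delegated to external tools such as Haplogrep).
Every sample yields two profiles — all useful reads, and damaged-only reads —
and the contamination screen compares them at sites covered ≥ 10× in both:
any discordant call, or more than one mixed base in the all-reads profile,
raises a "possible contamination" flag; an effectively empty damaged profile
is "not evaluable".

## The simulator

The simulator generates what the pipeline consumes, with a truth row per read:
template molecules spanning an amplicon's full primer-to-primer interval on a
random strand; deamination applied once per template (probability
p_bg + p_max·λ^z per C at 5'-distance z, mirrored for G), so PCR duplicates
inherit identical damage — which is precisely what makes exact-sequence
deduplication meaningful; geometric duplicate counts (mean configurable);
per-read uniform sequencing errors emitted as the matching constant Phred
quality; adapter read-through when the template is shorter than the read; and
optional contamination, where each molecule is drawn with fixed probability
from a second, undamaged reference (a planted present-day profile).

One interaction worth understanding when designing contamination scenarios:
because the contaminant is undamaged, its PCR duplicates are sequence-identical
and collapse under exact-sequence deduplication, while damaged endogenous
templates survive as distinct sequences. An undamaged contaminant therefore
only retains its planted mixture fraction after deduplication when the library
is duplicated enough that error-bearing copies preserve its diversity — which
is exactly the regime of real amplicon libraries. The package's contamination
fixtures use a mean duplicate count of 8 per molecule for this reason.

It deliberately does not emulate: empirical position-dependent quality
profiles, indels (the pipeline ignores them), optical duplicates, or
fragmentation-length variation within an amplicon (molecules always span the
full insert; real libraries also contain shorter fragments). Passing tests
therefore demonstrate correctness of the algorithms under the stated model,
not robustness to every artefact of real instruments. Tests run against a
seeded uniform-random synthetic reference of rCRS length; base composition of
the real NCR (C-rich, with homopolymer tracts) differs, which affects absolute
damage-percentage levels but none of the exactness properties.

## Problem sizes and numerical choices

Test and acceptance simulations use 10^4 reads for damage-percentage
estimates (binomial standard error ≈ 0.5 percentage points at 50%), 10^3–10^4
molecules for library-structure checks, and exhaustive enumeration (all 1369
positions) for coordinate properties — sizes at which the checked quantities
are stable to well within the asserted tolerances. Score equivalence against
the brute-force evaluator is asserted to 10^−9 (pure floating-point
reassociation). Determinism: every stochastic component takes an explicit
seed, and identical inputs yield byte-identical outputs; the simulator
restores the caller's RNG state. Degenerate inputs are return states, not
errors: empty FASTQ yields a diagnostic summary row, unmapped reads and
dropped reads are reported as such, and a zero denominator in the duplication
rate is defined as 0 with a warning.

## Known limitations

The aligner is ungapped and single-reference by design; reads from outside
the NCR window simply fail to map. Mapping quality is a proxy, not a
probability. The damage model's end-anchored decay understates mid-molecule
deamination for amplicons far from fragment ends. Length heteroplasmy in
303–315 is out of scope. Haplogroup assignment is external. Inferential
statistics across sample cohorts (beyond descriptive tables and Spearman
correlation) are out of scope.
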