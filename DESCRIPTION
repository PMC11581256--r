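Package: mtamplicon
Title: Amplicon-Based NGS Analysis of the Human mtDNA Control Region from Degraded Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing amplicon-based next-generation sequencing data of the
    human mitochondrial DNA non-coding region (control region) from ancient and other
    degraded samples. Provides circular-reference linearization with bijective coordinate
    remapping, amplicon panel geometry, read preprocessing (adapter, poly-X, primer and
    quality trimming; paired-end merging), exact-sequence and coordinate-class duplicate
    removal, a k-mer seed-and-extend aligner with SAM interchange, per-read post-mortem
    damage (PMD) log-likelihood scoring and sample authentication, pileup-based variant
    and IUPAC mixed-base calling with HSD haplotype emission, a damaged-versus-all
    contamination screen, and a seeded simulator of degraded amplicon libraries
    (PCR duplication, terminal deamination, sequencing error, contamination mixtures)
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
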