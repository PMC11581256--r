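# Package-wide constants (loaded first in collation order).

DNA_BASES <- c("A", "C", "G", "T")

# Illumina TruSeq adapter sequences (default adapter set for trimming and the
# read-through padding in the simulator).
TRUSEQ_ADAPTER_R1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
TRUSEQ_ADAPTER_R2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"
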