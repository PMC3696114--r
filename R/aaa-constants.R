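# Shared constants (this file loads before the others).

BASES <- c("A", "C", "G", "T")

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

ALL_CODONS <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES, paste0))

SENSE_CODONS <- setdiff(ALL_CODONS, c("TAA", "TAG", "TGA"))
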