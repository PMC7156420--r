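# Shared fixtures: the synthetic stand-in amplicons shipped with the package
# and a couple of tiny hand-built amplicons for exhaustive checks.

fixture_amplicons <- mds_amplicons()

# 12-nt toy amplicon starting at the first codon: codons ATG CAA GGT TCA
toy_nt <- reference_amplicon("toy_nt", "toy", 1, "non_transcribed",
                             "ATGCAAGGTTCA", cdna_start = 1)
toy_t <- reference_amplicon("toy_t", "toy", 1, "transcribed",
                            revcomp_chr_test("ATGCAAGGTTCA"), cdna_start = 12)

# build synthetic post-demultiplex records for a set of families
make_records <- function(families) {
  do.call(rbind, lapply(seq_along(families), function(i) {
    data.frame(barcode = sprintf("BC%04d", i), target = families[[i]],
               stringsAsFactors = FALSE)
  }))
}
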