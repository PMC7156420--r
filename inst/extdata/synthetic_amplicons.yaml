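# Amplicon metadata for the synthetic stand-in references.
# cdna_start is the 1-based coding-strand cDNA coordinate of the read's FIRST
# target base; for transcribed-strand assays the read walks the cDNA backwards.
amplicons:
  - name: Kras_ex1_nt
    gene: Kras
    exon: 1
    read_strand: non_transcribed
    cdna_start: 10
  - name: Kras_ex1_t
    gene: Kras
    exon: 1
    read_strand: transcribed
    cdna_start: 69
  - name: Kras_ex2_nt
    gene: Kras
    exon: 2
    read_strand: non_transcribed
    cdna_start: 160
  - name: Kras_ex2_t
    gene: Kras
    exon: 2
    read_strand: transcribed
    cdna_start: 219
  - name: Hras_ex2_nt
    gene: Hras
    exon: 2
    read_strand: non_transcribed
    cdna_start: 160
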