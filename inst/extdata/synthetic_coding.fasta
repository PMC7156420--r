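>Kras_cds_synthetic synthetic coding-strand cDNA stand-in, codons 12/13/61 = GGT/GGC/CAA
ATGTGTACGGGGAGTAAGAGAAAGCCGACTGAAGGTGGCTACGATGGGGTTAGCGTTATA
TCCGGGGCAAGTTCGCTCGTGGGTGTGCGCTTCGGTGCCCGGGGTTTACTACCATCCAGG
CCACTAGCCGCACGCTTAGGTGAACGACTATATTATGATACGTTCCGAGCTAGAACTTGT
CAATCGACGTTACTAGACATTCCTTCTTACGTACCTGACGGGAATACTCACGGTGCCTTT
>Hras_cds_synthetic synthetic coding-strand cDNA stand-in, codons 12/13/61 = GGT/GGC/CAA
ATGAAGGCAGACCGAGTGTCCCGTCGAAATAGGGGTGGCCATGGACTCCCGAACTTAGTG
TTTTGCGGGAACCCGACGTGGCCTAATGAATACTCAATAGCGCCGAGACATCAGGTACAC
ATCGGTGGAAATTGCCACGGTATTGTTCGTACACGCCTCGTGACGCATAAGGTAGAGATT
CAACTATCCGAAGAGCCCATGAGAGGCTTCAGGTGGGCAAAATTACAATTCGCCCTGTTT
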