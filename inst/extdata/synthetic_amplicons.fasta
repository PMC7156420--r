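>Kras_ex1_nt synthetic stand-in, read orientation (non-transcribed strand), cDNA 10-69
GGGAGTAAGAGAAAGCCGACTGAAGGTGGCTACGATGGGGTTAGCGTTATATCCGGGGCA
>Kras_ex1_t synthetic stand-in, read orientation (transcribed strand), cDNA 69-10
TGCCCCGGATATAACGCTAACCCCATCGTAGCCACCTTCAGTCGGCTTTCTCTTACTCCC
>Kras_ex2_nt synthetic stand-in, read orientation (non-transcribed strand), cDNA 160-219
ACGTTCCGAGCTAGAACTTGTCAATCGACGTTACTAGACATTCCTTCTTACGTACCTGAC
>Kras_ex2_t synthetic stand-in, read orientation (transcribed strand), cDNA 219-160
GTCAGGTACGTAAGAAGGAATGTCTAGTAACGTCGATTGACAAGTTCTAGCTCGGAACGT
>Hras_ex2_nt synthetic stand-in, read orientation (non-transcribed strand), cDNA 160-219
GTGACGCATAAGGTAGAGATTCAACTATCCGAAGAGCCCATGAGAGGCTTCAGGTGGGCA
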