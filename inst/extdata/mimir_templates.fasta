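>shrna_neg_control
AAGCAACACGCAGAGTCGTAATCTCTTGAATTACGACTCTGCGTGTTGCTATAGTGAGTCGTATTA
>full_match
TCGCCCTGAACCTGAAACATATGACAACCATAGGTTTCAGCGTCAGGGCTATAGTGAGTCGTATTA
>seed_match
ATGGAGATGCGGAGAAACATATGACAACCATAGGTTTCTCGCCATCTCCTATAGTGAGTCGTATTA
>seed_supplementary
ATGGACTGACGGAGAAACATATGACAACCATAGGTTTCTCGCTCAGTCCTATAGTGAGTCGTATTA
>mismatch_10_11
TCGCCCTGAAGGTGAAACATATGACAACCATAGGTTTCACGGTCAGGGCTATAGTGAGTCGTATTA
>mismatch_10
TCGCCCTGAACGTGAAACATATGACAACCATAGGTTTCACCGTCAGGGCTATAGTGAGTCGTATTA
>mismatch_11
TCGCCCTGAAGCTGAAACATATGACAACCATAGGTTTCAGGGTCAGGGCTATAGTGAGTCGTATTA
>full_match_mrna
GCGTCACAAATTTCACAAATATGACAACCATAGTTGTGAAGGTTGTGACTATAGTGAGTCGTATTA
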