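>mcherry_mrna_nematostella_zebrafish
TAATACGACTCACTATAGTGTTAAACCAACCAACCACCATGGTGAGCAAGGGCGAGGAGGATAACATGGCCATCATCAAGGAGTTCATGCGCTTCAAGGTGCACATGGAGGGCTCCGTGAACGGCCACGAGTTCGAGATCGAGGGCGAGGGCGAGGGCCGCCCCTACGAGGGCACCCAGACCGCCAAGCTGAAGGTGACCAAGGGTGGCCCCCTGCCCTTCGCCTGGGACATCCTGTCCCCTCAGTTCATGTACGGCTCCAAGGCCTACGTGAAGCACCCCGCCGACATCCCCGACTACTTGAAGCTGTCCTTCCCCGAGGGCTTCAAGTGGGAGCGCGTGATGAACTTCGAGGACGGCGGCGTGGTGACCGTGACCCAGGACTCCTCCCTCCAGGACGGCGAGTTCATCTACAAGGTGAAGCTGCGCGGCACCAACTTCCCCTCCGACGGCCCCGTAATGCAGAAGAAGACCATGGGCTGGGAGGCCTCCTCCGAGCGGATGTACCCCGAGGACGGCGCCCTGAAGGGCGAGATCAAGCAGAGGCTGAAGCTGAAGGACGGCGGCCACTACGACGCTGAGGTCAAGACCACCTACAAGGCCAAGAAGCCCGTGCAGCTGCCCGGCGCCTACAACGTCAACATCAAGTTGGACATCACCTCCCACAACGAGGACTACACCATCGTGGAACAGTACGAACGCGCCGAGGGCCGCCACTCCACCGGCGGCATGGACGAGCTGTACAAGTAAGACTCTAGATCATAATCAGCCATACCACATTTGTAGAGGTTTTACTTGCTTTAAAAAACCTGAAACATACCCACACCTCCCCCTGAACCTGAAACATAAAATGAATGCAATTGTTGTTGGAAACATATTAACTTGTTTATTGCAGCTTATAATGGTTACAAATGAAAGCAATAGCATCACAAATTTCACAAATAGAAGCATTTTTTTCACTGC
>mcherry_mrna_zebrafish_cleancap
TAATACGACTCACTATAAGTGTTAAACCAACCAACCACCATGGTGAGCAAGGGCGAGGAGGATAACATGGCCATCATCAAGGAGTTCATGCGCTTCAAGGTGCACATGGAGGGCTCCGTGAACGGCCACGAGTTCGAGATCGAGGGCGAGGGCGAGGGCCGCCCCTACGAGGGCACCCAGACCGCCAAGCTGAAGGTGACCAAGGGTGGCCCCCTGCCCTTCGCCTGGGACATCCTGTCCCCTCAGTTCATGTACGGCTCCAAGGCCTACGTGAAGCACCCCGCCGACATCCCCGACTACTTGAAGCTGTCCTTCCCCGAGGGCTTCAAGTGGGAGCGCGTGATGAACTTCGAGGACGGCGGCGTGGTGACCGTGACCCAGGACTCCTCCCTCCAGGACGGCGAGTTCATCTACAAGGTGAAGCTGCGCGGCACCAACTTCCCCTCCGACGGCCCCGTAATGCAGAAGAAGACCATGGGCTGGGAGGCCTCCTCCGAGCGGATGTACCCCGAGGACGGCGCCCTGAAGGGCGAGATCAAGCAGAGGCTGAAGCTGAAGGACGGCGGCCACTACGACGCTGAGGTCAAGACCACCTACAAGGCCAAGAAGCCCGTGCAGCTGCCCGGCGCCTACAACGTCAACATCAAGTTGGACATCACCTCCCACAACGAGGACTACACCATCGTGGAACAGTACGAACGCGCCGAGGGCCGCCACTCCACCGGCGGCATGGACGAGCTGTACAAGTAAGACTCTAGATCATAATCAGCCATACCACATTTGTAGAGGTTTTACTTGCTTTAAAAAACCTGAAACATACCCACACCTCCCCCTGAACCTGAAACATAAAATGAATGCAATTGTTGTTGGAAACATATTAACTTGTTTATTGCAGCTTATAATGGTTACAAATGAAAGCAATAGCATCACAAATTTCACAAATAGAAGCATTTTTTTCACTGC
>sfgfp_mrna_zebrafish
AATACACTTGTTCTTTTTGCAATATTCAAGCTCATCGATTCGAATTCATGCCTAAGAAGAAGAGAAAGGTGGTGTCTAAAGGAGAGGAGCTGTTCACAGGCGTGGTGCCAATCCTGGTGGAGCTGGATGGAGACGTGAACGGCCACAAGTTCAGCGTGAGAGGCGAGGGAGAGGGAGACGCCACAAACGGCAAGCTGACACTGAAATTCATCTGCACAACAGGCAAACTGCCTGTGCCTTGGCCAACCCTGGTGACAACCCTGACATACGGAGTGCAGTGCTTTAGCAGATACCCTGATCACATGAAACAGCACGATTTCTTCAAGAGCGCCATGCCTGAGGGCTACGTGCAGGAGAGAACCATCAGCTTCAAGGATGACGGAACCTACAAGACAAGAGCCGAGGTGAAGTTTGAGGGAGATACACTGGTGAACAGAATCGAGCTGAAAGGCATCGATTTCAAAGAGGATGGCAACATCCTGGGACACAAACTGGAGTACAACTTCAACAGCCACAACGTGTACATCACAGCCGATAAACAGAAGAACGGCATCAAAGCCAACTTCAAGATCAGACACAATGTGGAGGATGGATCTGTGCAGCTGGCCGATCACTACCAGCAGAACACACCTATCGGAGACGGCCCAGTGCTGCTGCCAGATAACCACTACCTGAGCACACAGAGCGTGCTGTCTAAAGACCCTAACGAGAAGAGAGATCACATGGTGCTGCTGGAGTTTGTGACAGCCGCCGGAATCACCCTGGGCATGGATGAGCTGTACAAACCTGCTGCTAAGAGAGTGAAACTGGATTAGCTCGAGGATGCTAGGAGATCTGAGTTCAAGGATCCTGATTGTGGTAGTGATCTGCCTTTCTTTCTTTTTTTTTTTTTGCCTGATCATCTCACACCCTTTCTTTCTTTTTTTTTTTTTGCCTGATCCATGACTCCTGTGATGGTATCTAGAACTATAGTGAGTCGTATTACACTAGTAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
>egfp_mrna_hydractinia
TAATACGACTCACTATTAGGTGTTAAACCAACCAACCACCATGGTATCCAAGGGCGAAGAATTATTTACTGGTGTTGTACCCATATTGGTGGAGCTCGACGGAGATGTAAATGGACACAAGTTCAGTGTGTCTGGGGAAGGAGAAGGAGATGCCACCTATGGAAAGCTGACTTTAAAGTTCATCTGTACTACGGGCAAGTTGCCTGTTCCTTGGCCTACACTTGTCACAACTCTGACATATGGTGTTCAATGCTTTTCGCGGTATCCGGATCATATGAAGCAGCACGATTTTTTTAAGAGTGCGATGCCAGAAGGTTATGTTCAGGAAAGGACCATATTTTTCAAGGACGATGGAAATTATAAAACCAGAGCTGAGGTAAAATTTGAAGGAGATACATTGGTTAATCGCATTGAATTAAAAGGAATCGATTTTAAAGAGGATGGTAACATCCTCGGTCATAAACTTGAGTATAACTACAACTCACATAACGTCTACATAATGGCTGATAAACAAAAAAATGGCATTAAAGTCAACTTTAAAATACGTCATAACATTGAAGACGGTTCAGTCCAACTTGCCGATCACTATCAACAAAACACTCCTATTGGTGACGGTCCAGTTTTGTTACCAGACAACCACTACCTATCTACACAAAGCGCCTTAAGCAAAGACCCAAATGAAAAAAGAGATCATATGGTTTTGCTGGAATTTGTTACAGCAGCTGGAATTACACTAGGAATGGATGAATTATACAAATAAGACTCTAGATCATAATCAGCCATACCACATTTGTAGAGGTTTTACTTGCTTTAAAAAACCTGAAACATACCCACACCTCCCCCTGAACCTGAAACATAAAATGAATGCAATTGTTGTTGGAAACATATTAACTTGTTTATTGCAGCTTATAATGGTTACAAATGAAAGCAATAGCATCACAAATTTCACAAATAGAAGCATTTTTTTCACTGC
>mcherry_mrna_hydractinia
TAATACGACTCACTATTAGGTGTTAAACCAACCAACCACCATGGTCTCGAAAGGAGAAGAGGATAATATGGCTATAATTAAGGAATTTATGCGCTTTAAAGTGCACATGGAGGGCTCCGTGAACGGACACGAATTTGAAATTGAAGGCGAAGGTGAGGGAAGACCATACGAAGGAACACAGACCGCTAAACTTAAGGTCACAAAGGGCGGTCCATTACCATTTGCATGGGACATCCTTTCACCCCAGTTCATGTACGGAAGCAAGGCATACGTTAAACATCCCGCTGACATCCCCGACTACTTGAAGTTGAGCTTTCCAGAGGGATTTAAGTGGGAAAGAGTGATGAATTTCGAGGATGGAGGGGTTGTTACGGTAACCCAAGATTCCAGTCTCCAGGACGGGGAATTTATCTACAAGGTAAAGCTAAGAGGTACAAATTTTCCGAGTGATGGGCCTGTTATGCAAAAGAAGACAATGGGTTGGGAAGCCAGCTCCGAGCGCATGTACCCCGAAGACGGAGCTTTAAAAGGAGAAATCAAGCAGCGACTGAAATTGAAAGATGGAGGTCATTATGATGCAGAAGTTAAAACTACTTACAAAGCCAAAAAACCAGTTCAGTTACCAGGTGCATATAATGTTAACATAAAACTAGACATCACATCACACAACGAGGACTATACGATCGTTGAACAATACGAGCGCGCGGAGGGTAGACATTCTACCGGTGGAATGGACGAGCTATATAAATAAGACTCTAGATCATAATCAGCCATACCACATTTGTAGAGGTTTTACTTGCTTTAAAAAACCTGAAACATACCCACACCTCCCCCTGAACCTGAAACATAAAATGAATGCAATTGTTGTTGGAAACATATTAACTTGTTTATTGCAGCTTATAATGGTTACAAATGAAAGCAATAGCATCACAAATTTCACAAATAGAAGCATTTTTTTCACTGC
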