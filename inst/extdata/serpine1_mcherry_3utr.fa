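>mCherry-Serpine1-3UTR construct, KpnI..NotI
GGTACCCGCCACCATGGTGAGCAAGGGCGAGGAGGATAACATGGCCATCATCAAGGAGTTCATGCGCTTCAAGGTGCACA
TGGAGGGCTCCGTGAACGGCCACGAGTTCGAGATCGAGGGCGAGGGCGAGGGCCGCCCCTACGAGGGCACCCAGACCGCC
AAGCTGAAGGTGACCAAGGGTGGCCCCCTGCCCTTCGCCTGGGACATCCTGTCCCCTCAGTTCATGTACGGCTCCAAGGC
CTACGTGAAGCACCCCGCCGACATCCCCGACTACTTGAAGCTGTCCTTCCCCGAGGGCTTCAAGTGGGAGCGCGTGATGA
ACTTCGAGGACGGCGGCGTGGTGACCGTGACCCAGGACTCCTCCCTGCAGGACGGCGAGTTCATCTACAAGGTGAAGCTG
CGCGGCACCAACTTCCCCTCCGACGGCCCCGTAATGCAGAAGAAGACCATGGGCTGGGAGGCCTCCTCCGAGCGGATGTA
CCCCGAGGACGGCGCCCTGAAGGGCGAGATCAAGCAGAGGCTGAAGCTGAAGGACGGCGGCCACTACGACGCTGAGGTCA
AGACCACCTACAAGGCCAAGAAGCCCGTGCAGCTGCCCGGCGCCTACAACGTCAACATCAAGTTGGACATCACCTCCCAC
AACGAGGACTACACCATCGTGGAACAGTACGAACGCGCCGAGGGCCGCCACTCCACCGGCGGCATGGACGAGCTGTACAA
GTAGCTCGAGCAGTGGGAAGAGACGCCTTCATTTGGGACGAAACTGGAGATGTTATAAGCAGAAACTCTGAAGAAAAGGA
TTATTTAAAGGACTCTATGGGGAGAAAGAGAAGGCAACTCCTCCTTACCCCCCACACTGGTAATCTTTCCAACCAGCATC
CCAGACCTCGGACTCTTGAAGGGAAAAGAGTCTAACTCCCTCCTCCCTAGGGATTCCTACCCCACAAAGGTCTCATGGAC
CATAGAACTCACAGTACCTGGATCTGCCCAGCATGCCCTTTGGACCCAGTTCCCACCGAGGCCCCAGCAGAGTGGAGGGC
ACAACACTTTCATTCAGCAAAATCGTTTGTGTTCCAGTCACACTGTGGGCACCTCTTGCATCGCCTGCCATTGCTGTGGA
GGGTGGCCATGGGCCAAAGGAAAAAGCACTGTCCTATCTCAAGGTCCACTGTGGAAATGTCCACCTTGCCCACCTCCAAG
GGGCAACGGATAGACAGATCAAATGGTGGCCCAATAGCGAGCCTTCTCCCTGCTCCCTCCCTTGACACAGCTTGCTTATG
TTATTTCACGCGTAGAGTGTAGGTGACTTGTTTACAGAGCTCCAGCTTTTTTCGACCCACAAACTTTTTTCATTTGGAAA
GGGTGTAAGAAAAGTCGGACGTGTGTGTGCCTGGCTCTTCGTCCCCAGTCTCCCAGTGGGGGGGCCCTGGGGAGATTCCA
GGGGTGTGATTGAATATTTATCTCTTGCTCTTGTATGTTTGTTGGGGAGAAGAAGCACTTTTAAGGAAAATGCTTCTTAT
TTAAACCGTGGCATACGGCATCCCATTTGGGGTCTGCATCCCTGTATGTCAGGGGTGCATCACTCCACAAACCTGCCCCT
CTGGGTAGCCTCGTGATGGGGCTCACACTGCCGCCTAGTGGCAGCCGAACACACCCTTACCCGGTCCCTCCCTCCCTCCC
CCCCCCCCCCCCCCCCCCCCGTGGCTCTTTTCCTTAGGGACCTTGCCAAGGTGATGCTTGGCAACCCACGTTAAAGGAAG
GGGGGAAAAAAGATTAGATGGAAGAGAGAGAGATTTGAGAGAGGGCAAAGTGGTTTCAAATTTTTCCAAGGCATTCAGAA
GCAGAGAGGGAAAAGGGGCTGTGTGACCTAACAGGACAGAACTTTCTCCAATTACTGGGTGAGTCAGAGCTGCACTGGTG
ACTCACTTCAATGTGTCATTTCCGGCTGCTGTATGTGAGCAGTGGACACGTGGGGGGGCGGGGGGGGGATGAAAGAGACA
GCAGCTCCTGGTCAACCACCTTAGTTAGATAATCTTTTTTGAAAGCTTCCTAGCTGGAGGTATGATCAGAAAACCAATTT
ACTGAAAAACTGCACAAGAAGGTACGGTGAATGTAATTTCCTAGCAGGCCACTCTGCATCTGTTATGTCTCCACCGGAAA
AAAAATAATCATGTTGGTGTTTTTGCTTTTCTCTCTCTCCCTCTTTCTCTCTGATTTTTTTTTCCTCTCTTTTCATTATG
CACTGGACAGCCACACACCGTGTACCCATAGGGCCCCAAATGTGGGGTCACATGGTCTTGAATTTTGTTGGTTACATATG
CCTTTTTGTTGTTGTTTGTCTTCACTTTTGATATATAAACAGGTAAATATGTTTTTTAAAAAATACTAAATATAGAGAAT
ATGCAAACAAAAGCGGCCGC
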