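>rdna_unit_synthetic length=2500 note=synthetic rRNA-like tandem-repeat unit for fixtures
ACTGCAATGTCAGAGCAAAAAAACATAACTAAGAGGAGATAATAATTTGTTCATGTCAGAGCGATAACGGGCTCGTTAAC
GCCAATACATAGCTCTCACGAAACGGCGCATCGCTGGCCCTACGTATGCCGATAACAATGCGTAAAAGGCCGGAGGGACG
CAAGGCGTGCGTCCTTGCTGCTACACAGTAACTAGCGGCGGTACTAGAATCTGCCCTATGCAACGACAGTACGGGCTCGT
GTGCGCTGTGTAACCAGGGCGGTCACCGAAGCGTAAGGGCTAACGCTACGTGTCCAGCCCTGTTCCATTAGAGCGCTCTT
AAGCTTTTTTGTCATCAGCTGGGTCCCAGACTAATCCAGGGCCTCCTTTTGTAGGCGCTTATCGCTTCGTAAGGTTACCG
TTTTTGTTATGTTCACCCAGTGAAGTAGTATTTCCAACTCATGCACCGCTCCTGAAGGTCGTGAGCGTCCGTTCCTTTGA
GTCTCGTTCCAAAGGCAAGGACTGGTGTTTATTAATAACTTGCCAAACGGCGCCGCGGGGCGCCGTCGGCTGATCCCATA
ACGGACTCATGGAAGTTTTAATGGGACTAACGCTCGTTCAGACGCTAATATCTTTAGGCATTGGTCTACTCAGTCAAATC
TGTTCCTTGCAGCCGTATCCGTCATGTATCACAGTATTGTTGCAGAGAGGAGACAGACCAGCTTACACGACAACCCTTGG
ACAACCACAGCCGGGTCACGGTCACTTGTTCTCTAACACCTAATGACACACAAAAACATAGACGATGTTACCTGTAGGTC
CCCAGGAAATTCATAAGACGTCTGTGGTGGGAGAAGTTAACGCGCCTAATACGCGCCCGCAAGAAGATCGTCACCACGAG
CTGTGGTGGGGCGATTTCACCCTTGACAGCGCTTTCTTACAATGAATCCATTCTTCTAATGAATAACTTGAAGTGAAAGT
AAAGATTTAGGGCAAATCTTTGTAGGAAGCAGACTGTAGCAAGTGCCCAAGCCCTGTCAGTTCATAATGCGCACCGTCCG
ATCATATGACCTAGAGTGCGCATGAAAACGGACACGTAATTCGGCGGTTCCTACGGGAGAGGATCCTTGTCGACCATCGA
AACAAAAAGGAGGTTGCCGCCAGGAGTGAGCTGCCTAACCAGATATGACGTTACTAGACGCGGAACTTTATGACTTCTCC
TGCTGCCCTATCCCTCATACATAACGTATATTCTAGGCCTACCAAGCGGGGAGTCCACCACCGAGTACATCAAATACACC
ATACGAAGCCACAAACGGCACGCCACTGTAAGAGCGCATAACTCTTTACAGAAGGATCACAAAAGCATGTCGGTATAACT
TTCTCGATAATCCTCAAGACTCTTCGTGAAATTCTTACGTGGTCACATATTGTTAGTATGAGTGTAATCCTGAGGTTCCG
CCTGTCACTCTTGAGGTCCGTGATCAAAATCCAGAGAACGGGCTCGCGTGGGCTCCGTCCGCACTTTAGCCCGAGTAAGG
AGTTCTTGGACAAATCATCCGAGAAGGAAGGTAGTGACTGAAGCAAGAAGGAGGTGTACTCCGAAAGTCCCCACGAGCAC
GGGAAGGGATCGGTCAAGATCGACGGGTTTGGATGGAACATATACGAGAAGCCTCGTCCTTACCGACGAATGGCACGAAG
TTCACACAGCACTGTCCATACAGACTTGACCACGGTTAGCATCCAGGTACGGCCCTTAGACTTTAGGGGAATTTGCTACT
CGATTTTGGCGCATTGAGATACAAAGCCGGAACAAAACGGACCCCTAAAGCGCGGTGGAATGCGAAACAGCAACGCAGCC
TGAGAGTAGGTCCGGGAGCTACTAATACTCTCATCCCGCCAGGTCAGCCGAGTAGGCGTTATCATATGCCATTGTATGTC
CTGGGAAAGTTCGTTGGTATCTGATATAACGAATATTGGATATAAAGTTGAACCCGTGACCCTTGCAGTTGTTACGGATT
GCAATCTTATCCCCCATCTAGTCACTCGATATAACGTATTCCATTATCTCTATTAGCACACTAATCCGCCTACCTCTGGC
TCAATAATTTCTTGGACAGGGTACGCGAAAACAGAGCATTAGATTTAGGGGCAAGCGGTTGCTAACGGTCCCACTCGCGG
GCCCCGTAGGTCCCTGTTAAGTTTTCAGATATTGGCATAGGTATGAGAAAATTCTCCTGGACATATTTAGATTTAATGGG
TATAGTTGACTCTTACCCAACTCCCATATTACTAGGACCATTGTCTCGGTCTTCTTTCAGCGGAAGGTGCGATTGCACCT
CTGATTGAGACGATGTACCAGTCCCGACTAGCCTAGCTAAGCATGAGCTTTATGAGAGCGCAGGTACGATCCCACACAGC
TCACCGGCCTACACCTACTCTTCTTGTAATCCTCATGCATCCCTGCATAATTGATAATCATTCTCTGAGGGAGAGACTCT
CGATTTACTCAAAACCGGAG
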