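>A_1
AACGGACGATGCGTGTATGGCTGTGAGACTGAGCTCTACTCGAAACAACTTTCGTGCCACATAAGTGCAAGCTCAATCTA
CTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTTGCATACACAGCGGCTTTCGTT
GAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGTGGTGATCGGTACAACTTAAGAAAACCCATCTACAGTA
CTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATATACGACCAATCTAAGGAGCGGCTGTGAAAAGATCTCTGACTATCACAACCGTGAATGTCAGA
TGGATCCAGATGGCTCTTGTCTACTGTCTATTATTTTATC
>A_2
AACGGACGATGCGTGTATGGCTGTGAGACTGAGCTCTACTCGAAACAACTTTCGTGCCACATAAGTGCAAGCTCAATCTA
CTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTTGCATACACAGCGGCTTTCGTT
GAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGTGGTGATCGGTACAACTTAAGAAAACCCATCTACAGTA
CTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATATACGACCAATCTAAGGAGCGGCTGTGAAAAGATCTCTGACTATCACAACCGTGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTACTTTATC
>B1_1
AACGGACGATGAGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGTAAGCTCAATCTA
CCCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTT
GGGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTT
CTTAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGGAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGCAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCTAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATAGACGACCAATCTAAGGAACGGCCGTGAAAGGATCTCTGACTATCTCAACCGTGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTATTTTATC
>B1_2
AACGGACGATGGGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGTAAGCTCAATCTA
CCCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTT
GGGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTT
CTTAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGGAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGCAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCTAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATAGACGACCAATCTAAGGAACGGCCGTGAAAGGATCTCTGACTATCTCAACCGTGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTATTTTATC
>B2_1
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTA
CTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGCTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTT
GAGGGCTTGATAATGGTGGTCCACGTTGATAAAATCATAGCGAGATGATTGGTACAACTTAAGAAGACTCATCTACAGTT
CTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGAGCTTGGCGAGTAAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTGAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCGAATATACGACTAATCTATGGAACGGCCGTGAAAGGATCTCTGACTCTCACAACCGCGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTGTTTTATC
>B2_2
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTA
CTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGCTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTT
GAGGGCTTGATAATGGTGGTCCACGTTGATAAAATCATAGCGAGATGATTGGTACAACTTAAGAAGACTCATCTACAGTT
CTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGAGCTTGGCGAGTGAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTGAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATATACGACTAATCTATGGAACGGCCGTGAAAGGATCTCTGACTCTCACAACCGCGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTGTTTTATC
>OUTGROUP
AACGGGCGATGCGTGTATAGCTGTGAGACTAAGCTCTACTCGAAACATCTCTCGTGCCACATAAGTGCGAGCTCAATCTA
TTCATATCGCATCCCCAGACCACGAGGACCGTAGTTTCCATGTTCCGAAATAACGACTCGCACACACAGCGGCTTTTGTT
GAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAGCTTAAGAAAACCCATCTACAGTT
CTCAGCAACGCAGGAGGATCGTTGGTCTTACCTGGTGAAGTAATAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATATTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGACCTGTGAGTGACCAACGA
GTATGTCGATCTGCTCCTACTACTAAGAAGTGCGCCCCCGAATCAACGCTTAGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATATACGACCAATCTAAGGAACGGTCGTGAACGGATCTCTAACTATCACAACCGTGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTATTTTGTC
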