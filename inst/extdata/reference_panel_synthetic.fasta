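>BTN2|EF1a|G
TTTCAAAGCAGGGTGCGAATCCTAAAGTGGTCCACACGCACATCTCACTTCTTCCGAGTGGAGGCTCGCGGAGCAGACTA
ATTAAGGATACGCCCCCGCTAGGCCAATTGAACTATTCGATAGTGTAATTTAAAACATTGACGCCGGACAAGTACGACAA
TTTTCCGGGCGTTGACGTGTGCCACAGAATGAGACAATGGAGAACGCTCCCCAGTTGTGAGTAAAGTTAACTTGCTCACG
CGATTGAAGCGAGGGCCAATGGGGGAAGGTGCTTAACCTGCCATTTGGGTGTAGTCGCTACCTATTAACTCGCGCACGGT
TCCCGAGCCACCCTCCCTTAATCTTGACATAACTAACTGACAGAATGCCACCCAACGCTGCTCAAAGTATACGCAACGAT
TCTTCTCGTACCCGTCCCTATGCGCCAAAATGCAGATCCCTCCTCGATTA
>BTN2|EF1a|H
TTTCAAAGAAGGGTGCGAATCCTGAAGTGGTCCACACGCACATCTCACTTCTTCCGAGTGGAGGCTCGCGAGGCAGACTA
ATCAAGGATACCCCCCCGCAAGGCCAATTGAACTATTCGATAGTGTAACTTAGAACATTGACGCCGGAAAAGTACTACAA
TTTTCCGGGCGTTGACGTGTGCCACAGAATGAGACAATGGAGAACGCTCCCCAGTTGTGAGTAAAGCTAACTTTCTCACG
CGATTGAAGCGAGGGCCAATGGGGGAAGGTGCTTAACCTGCCATATGGGTGTAGTCGCTACCTATTAACTCGTGCACGGT
TCCCGAGCCACCCTCCCTTAATCTTGACATAACTAACTGACAGAATGCCACCCAACGCTGCTCAAAGTGTGCGCAACGAT
TCTTCACGTACCCGACCCTATGCGCCAAAATACAGATCCCTCCTCGATCA
>BTN2|COI|B
GCTCCTCGACTAACCCACCAATGGGCTTGGGCTCTCCGGGTCTCCAGTTGCGTCCTCACGCACCATTCGACCCCAATTCT
TGGTACATTATACCCGACACTTCCGATGGACATTCGGGCTCTACGAAGCTTTCCGCACTACGATCATCCTCCCCCTGATT
ATTACCTTATCTTCGTATGACGTACAGACACGGAGAGTGTCTCTAGCTTCCTGTCCACGCGAACCGTGGACAAGGCTACG
GTCCGTACTTTTCCGACAGAACTCTAGAGTCACCATCCACACCACTCCGCGGTGCTTGGGATGGCCGACGTAACTGCCTC
GACGGGGGATAATAGGCATAAGCCCCACGAGAGGCTGCGCGGCATCTGCCGTGTGAATAAAACTGAATTCATTCAGCGGT
TAGCCTAGATAGCTGTCTAAGATGTCGTCAGCCCGGGCTCTGTTATTGATGTGCGGCAGAGATACAAAAAAGGGTGGACT
TGCCACCGCAAAACCTGTAGCCTGCGTTCTGGATCTTATACACGCGGGGCCCCGCATTGTGGTCAAGGTACCTAGCGATC
AGAGCATACCAAAATCACCCGGTTTGGTACTTGGATGGTGATCTGGGAACGAACCTGGGTTCCAGCCCGT
>BTN2|CR|D
AGGCGCATGCCACGGACACAATGCAAGTAGAGGACCCGGCACATCTTTCAGCTTCTTATATGTAACGGGTGCTAGATAGC
CGCGGGATATCTTGGGAGTCCAACCTCGCTTACGGTTGATGCCGTGGGCCACCGCTAATCGGATCATGTCCTGAGGTGCG
AACCTTAAGTAGTTCGCTGCAAATCTTTTGGAGTGATACCTGCGTACACAATATTAAGTTGTGTGTATTACGGAATGGTT
CGGGTCGAGATCAAAGCGTTGATCCCTCTCGAGGGAAAAACGCAGCCCTCGAAAAGTTGACTAAATTCCAACCGCAGACC
ATCTTACGGAAAGGTTCAGTGTTTCTTAGTTAAAATTAATGTGACGCCAGATGTTAGGCGGATCAGTGAAAGAAGCCCGG
GCCCTTTGGATCGAAATAAATTAAGGCAAACGTATTTATTGGACTCCCGTTTCTCGGCTCTGATCTATCGAGAGTTCTCC
TGCTGGGGACATAGTAAGACAATGACCAGAGCGATGTAAAAGGAGACAAAAGAAATTATGAAAATAAGCCGTATTAAGCG
ACGTGTGTCGAAACTCGCGGGCTCTAAGGCACCACAGGGTTTTTTTGCTAGCTAAGCAGAAA
>BTN2|CR|C
AGGCGCATGCCACGGACACAATGCCAGTAGAGGACCCGGCACATCTTTCAGCTTTCTATATGTAACGGGTGCTAGATAGC
CGCGGTACATCTTGGTAGGCCAACCTCGCTTACGCCTGATGCCGTGGGCCACCGCTAATCGGATCAAGTCCTGAGGTGCG
AAGCTTAAGTAGTTCGCTGCAAATATTTGGGAGTGATACCTGCGTACACAATATTAAGTTCTGTGTATTACGGATGTGTT
GGGGTTGAGATCAAAGCGTTGATCCAACTCGAGGGAAAAAAGCAGCCCACAAAAAGTTGACTAAATTCCAACCGCAATCC
ATCTTATAGAAACGTTCAGTGTTTATTAGTTAAGATTAATGTGACGCCAGATGTTAGGCGGCTCAGTGAAAAAAGCCCGG
GCCCGTTGGATCGAAATAAATTAAGGCAAACGGATTTATAGGACTCCCGTTTCTCGGCTCTGATCTATAGAGAGTTCTCC
TGCTGGGGTCATAGTAAGACAAGGACCAGAGCTATATAAAAGGAGACACAAGAAATTATGAAGATAAGCTGTATTAAGCG
ACGTGTGTCGAAACTCACGTGCTTTAAAGCACCACCTGGTTTTTTTACTAGCTAAACAGAAA
>BTN1|EF1a|BTN1-EF1a
TTTCAAAGCCGGGACCGAATCCTAAAGTGGTCCACACGCACATCTCACCTCTCCCGAATGGAGGGTCGCGGTGCTTACTA
ATTAAGGACACAAACCCGATAGGCGGATTGAACTTTTCTATAGTGTGGATTCAAACATGGACGCCGGATAACTACGACAA
ATTTCCGGCCGTTGACGTGTGCCAGAGAATGAGACAAACGAGAATGCTCACCGGTTGTGAGTCAAGTTAATTTGCTCACG
AGTTTGAAGCGAGAGCCAATCGGGTAAGGTGCTTTACTTGCCATCTGGGTGTAATCGCTTCCTATTAACTCGCGGACGGT
ACCCCAGCCACCCTCCCTTAATCTTTACATAACTAACTGACAGCATGCCACCCAACGCTGCTCAAGGTATACCTAACGAT
TCTTCTGGGACACGTCCCTATGCGCCAAAAAGCAGATCCGTCCTCGAGTA
>BTN1|COI|BTN1-COI
GCTCCTCTACTAACCCACCAATGGGCTTGGGCTCTCCGGGTCTCCAGTTTCGTCCCCACGCACCATTCGACCCCAATTAT
GGGTACATTATACCCGACACTTCCACTGGACATTCGGGCTCTAGGAAGGTTTCCGCACTACATTCAGCCTGCCCCTGATG
ATTACCTTATCTTTGTATGACGTGAAGACACGGAGAGTCTCTCGAGCTTCCTGTCCACGCGAACCGTGGACAAGGCTACG
GTCGGTACTTTTCCGACAGAACTCTAGAGACACCATCCACACCACTCCGCGGTGCTTGGGATGTCCGACGTAACTGCCTC
GAAGGGGAATAATAGGCATAACCCCCACGAGAGGCTGCACGGCATCTGCCGTGTGAATAAAACTGAATTCATTCAGCGGT
AAGCCTAGATAGCTGTCTTAGATGTCGTCAGCCCCGCCTCTGTTATTGATGAGCGGCAGAGATAGAAAAAAGGGTCGCCT
TGACACCGCAAAACCTGTAGCCTGCGTCCTGGATCTTATACACGCTGGGCCCCGCATTGTGGTCAAGGCACCTAGCGATC
AGAGTATACCAAATTCACCCGGTGTGGTACTTGGATCGTCAACTGGGAACGATCCTGGGTTCCAGGCCGT
>BTN1|CR|BTN1-CR
AGGCGAATCCCACGGACACAATACAAGTAGAAGATCCGGCACATCTTTCAGCTTTTTATATGTAACGCGTGCTAGATAGC
CGCCGGGTAACTTGGTAGTCCAACCTCACTTAAGTCTGATGCCGTGGCCCCCCGCTAATCGGATCAAGTACTGATTTGCG
AAGCTTAGGTAGGTCGCTGTAAATCTCTTACAGTCATACCTGCGTTAATAATGTTGAGTCCTGTGTATTACGGAATGGTT
AGGGTAGTGCTCAAAGCGTTGATCCCACTCGAGGGCAAAACGGAACCCTCGAAAAGTGGACTAAATTCCAACGGCAGTCC
ATCTTATAGAAAGGTTCAGTGTTTCTGAGTTAAGATTAATGTGGCGCCGGATGTTAGGCGGATCAGCGAAAGAAGCCCGG
GCCCTTTGGCTCGAAATAAATTAAGGCAAACGAATTTATTGGACTCACGTTTCTCTGCTCTAATCTATAGAGAGTTCTCC
TGCTGGGGACATAGTAAGACTACGGCCCGAGCGATGTAAAAGGAGACACAAGAAGTTATGAAAACAAGCCGTATCAAGCG
ACGTGCGTCGAAACTCGCGGGATTTTAGGCACCACAGGGTTTTTTTACTAGCTAAGCAGAAA
>host_F|COI|F-COI
GCTCCTCGACTAACCCACCAATGGTCTTGGGCTCTCCGGGTCTCCAGTTGCGTCCTCACGCACCATTCGACCCCAATTAT
GGGTACATTATACCCGACAGTTCCGATGGACATTCGGGCTCTACGAAGCTTTCCGCACTACGACCATCCTCCCCCTGATC
ATTACCTTATCTTCGTGTGACGTACAGACACGGCGAGTGTCTCTAACTTCCTGTCCACGCGAACCGTGGACAAGGCTACG
GTCCGTTCCTTTCCGACAGAACTCTAGAGTCACCATCCACACCCCTCCGCGGTGCTTGGGATGGCCGTCGTAACTGCCTC
GACGGGGGATAATAGGCATAAGCCCCACGAGAGGCAGCGCGGCATCTGCCGTGTGAATAAAACTGAATTCATTCAGCGGT
AAGCCTAGATAGCTGTCTAAGATGTCGTCAGCCCGGGCTCTGTTATTGATCTGCAGCAGAGATACAAAAGAGGGTGGTCT
TGCCACCGCAAAACCTGTAGCCTGCGTTCTGGATCTTATACACGCGGGGCCCCGCTTTGTGGTCAAGGTACCTGGCGATC
AGAGTATACCAAAATCACCCGGTTTGGTACTTGGATGGTCATCTGGCAACGAGCCTGGGTTCCAGGCCGT
>host_F|16S|F-16S
TTAGTATAACCTACACGTAGCACGATCAAATCGGTGCCTCGAGCTTAGGGCATAGACAGTATATGGAAGCATAAGATTCT
GAGGGTTATAGGTCGCCAAATCAGAGCTAGGGCTCTGGGCAAGTAAAGAGATTGAGTCGGGACGGCAACATCTATCTTGA
TTCCTATCGTCGTGGAGAATGGTCTGCCTGATTGTTTATACGAGAATCAAGTCCAGCTATGTGCTTTAACAACAGTATCC
GGGATGGCGGAGGAACACCTGGAATTGGCGTAGCGATGTGGATGCGGTCCATAAGGGTGCCGGTGGTTACTTACTCAGTA
CCAACTCAGATTACAGTAAAGGCTCAGACGTCTGTCCGTGTAACTTTCACATGCGAACACGCCCGTCGTACTAAGATGGC
GGGTAACCGAACCGGCAGGGTGAAGACGACAAAAGGATGTAGCTATGAACCGTATATGCCTGGGCTGAAGGTTAAGGAGA
CCTCCACGCCGGCCGTCAGA
>host_M|16S|M-16S
TACGAATAAACTGCACGTAGCACGATCAAATAGGTGCCTGAAGCTTAGGGCATAGACAGTATATGGAAGCAGAAACTTCT
GAAGGTTATGGGTCGCCAAATCAGGTCTAGGGCTCTGCGCAAGTAAAGTGAGTGAGTCGGGACGGCGACATATATCTTGC
TCCCTATAGTCGTGGAGTATGGTCTGCCTGATTGTTTATACGAGAATCAAGTCCAGCTATGTGCTTTAACTACAGTATCC
GGGATGGCGGAGGAACATCTGGAATTGGCGTAGCGCTGTTCATGCGGGCCATAAGGGTGCCGGTAGTACCTTACTCATGA
CCAGCGCAGATTACAATAACGGCTCAGACGTCTGTGCGTGTAACCTTCACATGCGAACACGCCCGTCGTACTAAGACGGC
GTGTAACCGAACAGGCAGCGTGAAGACGACAAGAGGATGTAGCTATGAACCATATATGCCTGGGCTGGCGGTTAAGGAGA
CCTCCACGCCTGCCGTCAGA
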