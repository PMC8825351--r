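>340|TRAC*01 IMGT|TRAC|C-REGION|TR|TRA|None|01
ATATCCAGAACCCTGACCCTGCCGTGTACCAGCTGAGAGGCTCTAAATCCAATGACACCT
CTGTCTGCCTATTTACTGATTTTGATTCTGTAATGAATGTGTCACAAAGCAAGGATTCTG
ACGTGCATATCACAGACAAAACTGTGCTAGACATGAGGTCTATGGACTTTAAGAGCAACG
GTGCTGTGGCCTGGAGCAACAAATCCGATTTTGCATGTACAAGCGCCTTCAAGGACAGCG
TTATTCCAGCAGACACCTTCTTCCCCGGCACAGAAAGTGTCTGTGATGCCAACCTGGTTG
AGAAAAGCTTTGAAACAGATATGAACCTAAACTTTCAAAACCTGTCAGTGATTGGGTTCC
GAATCCTCCTCCTGAAAGTGGCCGGGTTTAATCTGCTCATGACGCTGCGGCTGTGGTCCA
GCTGA
>341|TRAC*02 TRAC_205_Ensembl_CDS|TRAC|C-REGION|TR|TRA|None|02
ATGAATGTGTCACAAAGCAAGGATTCTGACGTGCATATCACAGACAAAACTGTGCTAGAC
ATGAGGTCTATGGACTTTAAGAGCAACGGTGCTGTGGCCTGGAGCAACAAATCCAATTTT
GCATGTACAAGCGCCTTCAAGGACAGCGTTATTCCAGCAGACACCTTCTTCCCCGGCACA
GAAAGTGTCTGTGATGCCAACCTGGTTGAGAAAAGCTTTGAAACAGATATGAACCTAAAC
TTTCAAAACCTGTCAGTGATTGGGTTCCGAATCCTCCTCCTGAAAGTGGCCGGGTTTAAT
CTGCTCATGACGCTGCGGCTGTGGTCCAGCTGA
>342|TRAC*03 TRAC_201_Ensembl_CDS|TRAC|C-REGION|TR|TRA|None|03
ATGAATGTGTCACAAAGCAAGGATTCTGACGTGCATATCACAGACAAAACTGTGCTAGAC
ATGAGGTCTATGGACTTTAAGAGCAACGGTGCTGTGGCCTGGAGCAACAAATCCAATTTT
GCATGTACAAGCGCCTTCAAGGACAGCGTTATTCCAGCAGACACCTTCTTCCCCGGCACA
GAAAGTGTCTGTGATGCCAACCTGGTTGAGAAAAGCTTTGAAACAGATATGAACCTAAAC
TTTCAAAACCTGTCAGTGATTGGGTTCCGAATCCTCCTCCTGAAAGTGGCCGGGTTTAAT
CTGCTCATGACGCTGCGGCTGTGGTCCAGCTGA
>343|TRAC*04 TRAC_202_Ensembl_CDS|TRAC|C-REGION|TR|TRA|None|04
ATGAATGTGTCACAAAGCAAGGATTCTGACGTGCATATCACAGACAAAACTGTGCTAGAC
ATGAGGTCTATGGACTTTAAGAGCAACGGTGCTGTGGCCTGGAGCAACAAATCCAATTTT
GCATGTACAAGCGCCTTCAAGGACAGCGTTATTCCAGCAGACACCTTCTTCCCCGGCACA
GAAAGTGTCTGTGATGCCAACCTGGTTGAGAAAAGCTTTGAAACAGATATGAACCTAAAC
TTTCAAAACCTGTCAGTGATTGGGTTCCGAATCCTCCTCCTGAAAGTGGCCGGGTTTAAT
CTGCTCATGACGCTGCGGCTGTGGTCCAGCTGA
>344|TRAC*05 TRAC_203_Ensembl_CDS|TRAC|C-REGION|TR|TRA|None|05
ACTGGGGTAAACAACCTCTTCTTTGGGACTGGAACAAGACTCACCGTTCTTCCAGATATC
CAGAACCCTGACCCTGCCGTGTACCAGCTGAGAGGCTCTAAATCCAATGACACCTCTGTC
TGCCTATTTACTGATTTTGATTCTGTAATGAATGTGTCACAAAGCAAGGATTCTGACGTG
CATATCACAGACAAAACTGTGCTAGACATGAGGTCTATGGACTTTAAGAGCAACGGTGCT
GTGGCCTGGAGCAACAAATCCAATTTTGCATGTACAAGCGCCTTCAAGGACAGCGTTATT
CCAGCAGACACCTTCTTCCCCGGCACAGAAAGTGTCTGTGATGCCAACCTGGTTGAGAAA
AGCTTTGAAACAGATATGAACCTAAACTTTCAAAACCTGTCAGTGATTGGGTTCCGAATC
CTCCTCCTGAAAGTGGCCGGGTTTAATCTGCTCATGACGCTGCGGCTGTGGTCCAGCTGA
>345|TRAC*06 TRAC_204_Ensembl_CDS|TRAC|C-REGION|TR|TRA|None|06
ATGAATGTGTCACAAAGCAAGGATTCTGACGTGCATATCACAGACAAAACTGTGCTAGAC
ATGAGGTCTATGGACTTTAAGAGCAACGGTGCTGTGGCCTGGAGCAACAAATCCAATTTT
GCATGTACAAGCGCCTTCAAGGACAGCGTTATTCCAGCAGACACCTTCTTCCCCGGCACA
GAAAGTGTCTGTGATGCCAACCTGGTTGAGAAAAGCTTTGAAACAGATATGAACCTAAAC
TTTCAAAACCTGTCAGTGATTGGGTTCCGAATCCTCCTCCTGAAAGTGGCCGGGTTTAAT
CTGCTCATGACGCTGCGGCTGTGGTCCAGCTGA
>346|TRBC1*01 NW_001114291|TRBC1|C-REGION|TR|TRB|None|01
AGGACCTGAAAAAGGTGTTCCCACCCAAGGTCGCTGTGTTTGAGCCATCAGAAGCAGAGA
TCTCCCACACCCAAAAGGCCACGCTGGTGTGCCTGGCCACAGGCTTCTACCCCGACCACG
TGGAGCTGAGCTGGTGGGTGAACGGGAAAGAGGTGCACAGTGGGGTCAGCACGGACCCAC
AGCCCCTCAAGGAGCAGCCCGCCCTCGAGGACTCCAGATACTGCCTGAGCAGCCGCCTGA
GGGTCTCGGCCACCTTCTGGCACAACCCCCGCAACCACTTCCGCTGCCAAGTCCAGTTCT
ATGGGCTCTCGGAGGATGACGAGTGGACCGAGGACAGGGACAAGCCCATCACCCAAAAGA
TCAGCGCCGAGGTCTGGGGTAGAGCAGACTGTGGCTTCACCTCGGTGTCCTACCAGCAAG
GGGTCCTGTCTGCCACCATCCTCTATGAGATCCTGCTGGGGAAGGCCACCCTGTATGCTG
TGCTGGTCAGTGCCCTCATGTTGATGGCCATGGTCAGAGGAAGGATTTC
>347|TRBC1*02 IMGT000073|TRBC1|C-REGION|TR|TRB|None|02
AGGACCTGAAAAAGGTGTTCCCACCCAAGGTCGCTGTGTTTGAGCCATCAGAAGCAGAGA
TCTCCCACACCCAAAAGGCCACGCTGGTGTGCCTGGCCACAGGCTTCTACCCCGACCACG
TGGAGCTGAGCTGGTGGGTGAACGGGAAAGAGGTGCACAGTGGGGTCAGCACGGACCCAC
AGCCCCTCAAGGAGCAGCCCGCCCTCGAGGACTCCAGATACTGCCTGAGCAGCCGCCTGA
GGGTCTCAGCCACCTTCTGGCACAACCCCCGCAACCACTTCCGCTGCCAAGTCCAGTTCT
ATGGGCTCTCGGAGGATGACGAGTGGACCAGGACAGGGACAAGCCCATCACCCAAAAGAT
CAGCGCCGAGGTCTGGGGTAGAGCAGACTGTGGCTTCACCTCAGTGTCCTACCAGCAAGG
GGTCCTGTCTGCCACCATCCTCTATGAGATCCTGCTGGGGAAGGCCTCCCTGTATGCTGT
GCTGGTCAGTGCCCTCATGTTGATGGCCATGGTCAAGAGGAAGGATTTC
>348|TRBC2*03 IMGT000073|TRBC2|C-REGION|TR|TRB|None|01
AGGACCTGAAAAAAGTGTTCCCACCCAAGGTCGCTGTGTTTGAGCCATCAGAAGCAGAGA
TCTCCCACACCCAAAAGGCCACGCTGGTGTGCCTGGCCACAGCTTCTACCCCGACCACGT
GGAGTTGAGCTGGTGGGTGAACGGGAAAGAGGTGCACAGTGGGGTCAGCACGGACCCACA
GCCCCTCAAGGAGCAGCCCACCCTCGAGGACTCCAGATACTGCCTGAGCAGCCGCCTGAG
GGTCTCGGCCACCTTCTGGCACAACCCCCGCAACCACTTCCGCTGCCAAGTCCAGTTCTA
TGGGCTCTCGGAGGATGACGAGTGGACCGAGGACAGGGACAAGCCCATCACCCAAAAGAT
CAGCGCTGAGGCCTGGGGTAGAGCAGACTGTGGCTTCACCTCTGAGTCTTACCAGCAAGG
GGTCCTGTCTGCCACCATCCTCTATGAGATCTTGCTAGGGAAGGCCACCTTGTATGCCGT
GCTGGTCAGTGCCCTCGTGCTGATGGCCATGGTCAAGAGAAAGGATTCC
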