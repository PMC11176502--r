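>microbe_001
AACAAGTCGCCTAGAAAGGTACCGCTGGCATGTCACGCCTCCCGGGTGCCGTCTTCAACTTCATGACCCTCGTGCATCAC
>microbe_002
AACAAGTCGCCTAGAAGGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGGCTTCAACTTCATGACCCTCGTGCATCAC
>microbe_003
AACAATTCGCCTAGAAAGGTACCCCTGGCATATGACGCCTCCCGCTTGCCGTCTTCAACTACATGACCCTTGTGCATCAC
>microbe_004
AACAAGTCGCACAGAAAGGTATCGAGGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCAC
>microbe_005
AACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCTACTTCATGACCCTCGTGCATCAC
>microbe_006
AAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATGGTGTGAATACGCGAGTCGTCGGAAAGCAGCTGAAT
>microbe_007
AAAGCCTCAAGCCGGGGTCTTAGCATTGAGACAGCTTAATAAATCGTGTGAACACGTGAGTCGTCGGAACGCAGTTGAAT
>microbe_008
AAAGCCTTATGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAGTCGTGTGAACACGTGAGTCGTCGGATAGCAGTTGAAT
>microbe_009
TAAGCCTCAAGCCGGAGTTTAGGCATTGAAACAGCTGAATTAATCGGGTGAGTACGTGAGTCGTCGGACAGCAGTTGTAG
>microbe_010
AGAGCCTCACGCCAGTGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATATGTCAGTCGTCGGAAACCAGTCGAAT
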