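>t01
TTTTCCTTCGAATTATTTTGTTATGACGGATGGAAGAAACCAGGTCGTCTCAGTCGTATCTGGGGACAGAGTTTGTCGGCAAAACCTAGAACACAGCGTACATAGGTGTATTATGATTAG
>t02
CTTTGCCCCAAATAGTTTTGTCATGACGGATTAGAGACGCCGGATTGGGTCGGTTGGAACTGGGCACAGCTTTTGTCTGCCTAACTGAGAAGACAGGCATCACGGGTGTATAATCATTAG
>t03
ACTTACAGCCAACTACTTTGTGATGACAGATCGCAGGTTACCGTAAGACTCAGTCGGATCTCGGAGCGGGATTTGTCTAGTAATCTGAGAATAGAGCAACGAAGGGTGTAGCACTATGAG
>t04
CTTTGCCCCAGATAGTTTTGTCATGACGGATTAGAGACGCCGGGTAGGATCGGTTGGAACTGGGCACAGCGTTTGTCTGCCTAACAGAGAAAACAGTGATCAGGGGTGTATAATGATTAG
>t05
TCTTCCAAAGAACGAATTGGTGATGACAGATCGTAGGGGCCAGTTATCGCCAGTTGGAGCTGAGAGCAGCGGTTGTCTAGTCAACCGTGAAGAGAGCCACAAAGGGTGTATGATTATCAG
>t06
CCGTTCAACGAACTCCTTCGTCATGACAGATCACAGGCTCCCGTTTGATTCTGTGGGGGCTCAGTGCGGCCTTTGTCTAGTCATCCCAGAAAAGAGAAGGGAAGGGTGTATGATGATGAG
>t07
TATTGCTACGAATTAGTTTGTTATGACTGATAGGAAAAACCTGGTTGTCTCCGTTGGATCTGGGGACAGTGTCTGTCAGCATAACGTTGAACTTAGCACGAAGTGGTCAATTATCATTAG
>t08
TTTTTCTTCCAGTTAGTTTGTGATGACGGATGGCAAATACCGGGTGGTCTCTGTTGGATCTGGGGACGGACTGTGTCGGCCTAACCTAGAATACAGAGTGGAGTGGTGTATGGTCATTAA
>OUT
TCTTTCACCAAACTACTTTGTTATGACAGATCCATGATTCCAGTCCGTGTCTGTAGGATCTAGGAACAGCGTTTGTCAAGATATCAGGGAATACAGCGTCAATGGGTGTATTATGATGAG
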