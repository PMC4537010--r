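>IGHV1-S69*01 cys104=294
GCACACCGTCAGGACACCTCTTTTAGCGGACCTCGTCCGGTACGCGGCCCAGGTGCCAAATTCGTCAGCGCCTCCCGGGT
CACAGAGGGACATAAAGGGTCACGCGGAGACACATGCCGGGAGCCGTTTCCTCGTAAAGGCCATAACCCGCGTATGAACC
CACTGTCTCCTCTCAGACAGACACCGCGGGCGCGTGGCCAAAATTCGCTTCAGGCCGCCTCCTTGCGTATGTCTACCGCA
GACGGCTGTTGGGACTCTGCGGGTACATCTAGCTGGGGTACCGGTGGTCATTTGTGT
>IGHV2-S70*04 cys104=294
GCACACCGTCAGGACACCTCATTTAGTGAACCTCGTCCGGCACGCGGCCCAAATGCCAAATTCGTCTGCGCCTCCCAGGT
CACAGAGGGACATAAAGGGTCACGCGGAGACACTTGCCGGGAGCCGTTTCCTCGTAAAGGCCATAACCCGAGTATGAACC
CACTGCCTCCTCTCAGACAGACACCGCGGGCGCCTGGCCAAAATTCGCATCAGGCCGCCTCCTTGCGTATATTTACCGCA
GACGGCTGTTGGGACTCGGCGGGTACATCTAGCTGGGGTACCGGTGGTCATTTGTGT
>IGHV3-S30*18 cys104=294
GCACACCGTCAGGAGAACGCTTTCCGCGGACCTCGTCCGGTACGCGGCCCAGGTGCCAAATTCGTCAGCGCCCCCAGGGT
CACAGTGAGACATAAAGGGTCACGCGGAGACACATGCCGGGAACCGTTTCCTCGTAAAGGCCATAACCCGCGTATCAACC
CAGTGTCTCCTCTCAGTCAGACGCCGCGGGCGCGTGGCCAAAATTCGCTTCGGGCCGCCTCCTTGCGTATGTCTACCGCG
GACGGCGGTTGGGGTTATGTGGGTACATCTAGCTGGGGTACCGGTGGCCATTTGTGT
>IGHV4-S39*01 cys104=294
TCAAACCCTCGGGACACTGCCTTTAGCGGACCTCGTCCGGTACGCGGCCCAGGTGCCAAATTCGTCAGCGCCCCCCGGAT
CACCGAGGGACATAAAGGGTCACGCGAAGACACATGCCGGGAGCCGTATTCTCGTAAAGGCCATAACCCGCGTATGAACC
CACTGTCTCCTCTCAGACCGACACCGCTGGCGCGTAGCCAAACTTCGCGGCAGGCCGCCTCCTTGGGTATGGCTAGCTCA
GACGGCAGTTGGGACTCTGCGGGTACATCTAGTTGGGGTACCGGTAGTCAATTGTGT
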