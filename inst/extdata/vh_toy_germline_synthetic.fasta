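>IGHV1-11*01 class=V family=IGHV1 anchor=288
CCGAACAGTACGTCTCCGTTCGTTTCTACTTTGCCGTCCCCAGACGGCGGGGGCTACAGCCTGCTTACCTCTAGCGTTACCGTTAGTGAACTCCACCTACTTACTCCTGGTGAGGTTAAATTCGCCCCATTCAACGCAGTCATCGTTAGGGTACAGCGTAGTGCCACAGGCTTTCTACCCCACTACTACTTAATCGGGATAGAAATGATTGCTTTTGGATCTGTATCGGGAGTACGGGTAAGAGCGCAGCTAGACAGAGGGTTATCTGTGAAGCTAGCTTATTTCTGTTGC
>IGHV1-21*01 class=V family=IGHV1 anchor=288
CCGAACAGTACGTCTCCGTTAGATTCAACTTTGCCGTCCCCAAACGGCGGGGGCTACAGCCTGCTAAACTCTAGGGTTACCGTTAGTGGACGCCACCTACTTCCTCCTTGTGCGGTTAAAGTCGCCCCATTCAACGCAGTCATCGCAAGAGTACAGAGTAGTGCCACAGGCTTTCTATCCCACTACTACGTAATCGGGATAGAAATGATTGCTTTAGGGTCTGTTTCGGGCGTACGGGGAAGAGCGCAGCGAGTAAGAGGGTTATCTGTGGAGCTAGCTTATTTCTGTTGC
>IGHV2-12*01 class=V family=IGHV2 anchor=288
GGAAACAGGCCGTTTTTGGATAGACGCACCCTTGCGGGGAAATGGAACTTAACAGCTCAGGCCGAAGCCAGCGACCTGACTCCCCCGCCCGCCAGCGGAAGTCGGACCGAAAGGCCTGACGATGTGACATCAAACTCCCGACTCCGCTTGTGCGGCGGGACAACAGGGATTGACCTTCACTTGATGGCTGCGGTGGTCACAGACTCCCGCTCTCCACTCACTCGGCACCAATTATGGGACTCAGCGTGTACCCGCGACCATCGCGATCGTGTATTTGCTCTTTCTTCCTGC
>IGHV2-22*01 class=V family=IGHV2 anchor=288
GGAAATAGGCCGTTTTTGGATAGACGCACCCTTGCGTGCAAATGGAACTTTATAGCTCAGGCCGAAGCCAGCGACCTGACTGCCCCGCCAGACAGCAGAAGTTGGACCGAAAGGCCGGACGATGAGGCATCAAACTCCCGACTCCGCTTGTTCGGCGGGACAACACCGGTTGACCTTCGCTTGATGGCTGCGGGCGTCACACACTCCCGCTCTCCACGCACTCGGCACCAACTATGGGACTCAGCGTGTACCCGCCACGATCGCGATCTGGTATTTGCTCTATCTTCCTGC
>IGHV3-13*01 class=V family=IGHV3 anchor=288
CTTAACTGCAAAAGTATCATACATATTTACTCTAGTGTTCGGCCGGATCCCCCCCTTATTGGGTCTGGAGCATACTTCCTTGGTATGCTGCTATCTTATTATTCAAATATTTCTCGTGGCCAAATGCCCGGATCTACAGGGGGGTCGGACAAAGGTCTTGCCACGAACAGGTCTAAAAACCCGTGGGTGTACCAGAGGAACGAACAGTTATCAGACCACATTGACTTCCATATGCCTATTGTGTATCACGTCTTGTTCATAGTATTTGGGGATGTTATGACTGCTTACTGT
>IGHV3-23*01 class=V family=IGHV3 anchor=288
CTTAACTGCAAAAGTATGCTACATATTTACTTTAGTGCTCGGCCGGATCCCCCCATTATTGGGACTGGAGCTTACTTCCTTGGTGTACTGCTATCTAATGATTCAAATGTTTCACGTGGCCAAATGCCCGGATCTACAGGGGGGCCGGACAAAGGTCCTGACACCATCAGGTCTAAAAACCCCTCGGTGTCCCGGAGGAACGAAGAGTTATTAGACGAGATTGACTACCATATGCCTATTGTGTATCTCGTCTTGTTCATAGTATTTGGGGATGTTATGACTGCTTACTGC
>IGHV4-14*01 class=V family=IGHV4 anchor=288
GTAAACACTACTATAGTGGAGTCAAACTTACAAGGTTGGGCTGTGATATCCCACGGCATATGGTCAAGCCTAGGAACTGTGTCTGACCTCCCCTGCATATCCCCAGAAGGTCGCTTAGTCCAAGATCAGTCATACAGGACGGGCGCCATCCTACGCTGCGGAGGGTGCCTAACCTTTAGAGAAGTGTTTATGGAATCGTGTATGATCGGATGGACGCGTCCACGTACGATAGTTCTTTCTCTAGATAGCCGTTTAACGAGCCAATCTCTCGTTTACACTCCGATCAATTGT
>IGHV4-24*01 class=V family=IGHV4 anchor=288
GTAAACACTACTATAGTGGAGTCATACTTAAAAGCTTGGGCTGTGATATCCCACGGCATCTGGTCACCTCTAGGAACTGTGTCTGCCGTCCCCTGCAAATCCCCAGAAGGGCGCTTAGTCCAAGACCAGTCATTCAGGACGGGAGACATCCTACGCTGCGGAGGGTGCTTAACAAGTAGAGGTGTGTTTGTGGAATCGTGTATGATCGGATGGACGCGTCCACCTACGATAGTTCTATCTCTAGATAGGCGTTTAACGAGTCGATCTCTCGTTTACACTACGATCAATTGT
>IGHV5-15*01 class=V family=IGHV5 anchor=288
CCTACGCCACTGAGTAACTATTTCAGTAGGAGCGTCAATACCCTCGAAGCACATCTACGGGAGAGGACGCACAGGTTGATCTGCATGGTGTCGTTCTCCGGGCTTGGTGAGCAGCCACCATTCGTCGATAACCTGAAGTGCCTAACCCGGGTAATTGTAGCTGGAAGGAGGTCGTCCCGTCCGTCTCTGGGCCTGACGACAGCCTACGGGTGGGTCTATAGTAAAGCGCGCTGCCTTTACCGTGCAAGACGTGGCATAGGTTCGGCATGCGCCAGATATAGCTCGACTTGT
>IGHV5-25*01 class=V family=IGHV5 anchor=288
CCTACGCCACTCCGTAACCATTTCAGTAGGAGCGTCAACACCCTCGAAGCACATCTACCGGGGAGGACGCACAGGTTGATCTGCATGGTGTCGTTATCCGGGCTTGGTGAGCAGCCAGCATTCGTCGATAACCTGAAGTTCCTAACCCGGAGAATTGTAGCTGGAAGGAGGTCGTCCCGTACGTCTCTGGGCCTCACGACTCACTACGAGTGGTTTTGTAGTAAAGCGTGCAGCCATTACCCTGCAAGACTTGGCATAGGTTCGTCATGCGCCAGATATAGCTCGGCTTGT
>IGHJ1*01 class=J family=IGHJ anchor=6
GCCAGTTGGGGATACCTAACCCTGCGCCCTGTCTTTACAAACTCACAG
>IGHJ2*01 class=J family=IGHJ anchor=6
AATCCTTGGGATTATGCAGGCATGGCGCGTCCAAACGGGCAATTCACG
>IGHJ3*01 class=J family=IGHJ anchor=6
CGCGTATTCGGCAACGACTCGGGCATTGGACTCATTGTGAATCTAGAC
>IGHJ4*01 class=J family=IGHJ anchor=6
GGACTGTGGATATGGAGCGTCAAAACTGCTATGCACCGACGCCTTTAT
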