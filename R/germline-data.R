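# Packaged toy germline segment set (synthetic; generated once, fixed).
# V segments: 288 nt framework + conserved Cys anchor codon (anchor_offset 288).
# J segments: 6 nt upstream + conserved Trp/Phe anchor codon + 39 nt FR4 (anchor_offset 6).
.toy_v_names <- c("IGHV1-11*01", "IGHV1-21*01", "IGHV2-12*01", "IGHV2-22*01", "IGHV3-13*01", "IGHV3-23*01", "IGHV4-14*01", "IGHV4-24*01", "IGHV5-15*01", "IGHV5-25*01")
.toy_v_seqs <- c(
    "CCGAACAGTACGTCTCCGTTCGTTTCTACTTTGCCGTCCCCAGACGGCGGGGGCTACAGCCTGCTTACCTCTAGCGTTACCGTTAGTGAACTCCACCTACTTACTCCTGGTGAGGTTAAATTCGCCCCATTCAACGCAGTCATCGTTAGGGTACAGCGTAGTGCCACAGGCTTTCTACCCCACTACTACTTAATCGGGATAGAAATGATTGCTTTTGGATCTGTATCGGGAGTACGGGTAAGAGCGCAGCTAGACAGAGGGTTATCTGTGAAGCTAGCTTATTTCTGTTGC",
    "CCGAACAGTACGTCTCCGTTAGATTCAACTTTGCCGTCCCCAAACGGCGGGGGCTACAGCCTGCTAAACTCTAGGGTTACCGTTAGTGGACGCCACCTACTTCCTCCTTGTGCGGTTAAAGTCGCCCCATTCAACGCAGTCATCGCAAGAGTACAGAGTAGTGCCACAGGCTTTCTATCCCACTACTACGTAATCGGGATAGAAATGATTGCTTTAGGGTCTGTTTCGGGCGTACGGGGAAGAGCGCAGCGAGTAAGAGGGTTATCTGTGGAGCTAGCTTATTTCTGTTGC",
    "GGAAACAGGCCGTTTTTGGATAGACGCACCCTTGCGGGGAAATGGAACTTAACAGCTCAGGCCGAAGCCAGCGACCTGACTCCCCCGCCCGCCAGCGGAAGTCGGACCGAAAGGCCTGACGATGTGACATCAAACTCCCGACTCCGCTTGTGCGGCGGGACAACAGGGATTGACCTTCACTTGATGGCTGCGGTGGTCACAGACTCCCGCTCTCCACTCACTCGGCACCAATTATGGGACTCAGCGTGTACCCGCGACCATCGCGATCGTGTATTTGCTCTTTCTTCCTGC",
    "GGAAATAGGCCGTTTTTGGATAGACGCACCCTTGCGTGCAAATGGAACTTTATAGCTCAGGCCGAAGCCAGCGACCTGACTGCCCCGCCAGACAGCAGAAGTTGGACCGAAAGGCCGGACGATGAGGCATCAAACTCCCGACTCCGCTTGTTCGGCGGGACAACACCGGTTGACCTTCGCTTGATGGCTGCGGGCGTCACACACTCCCGCTCTCCACGCACTCGGCACCAACTATGGGACTCAGCGTGTACCCGCCACGATCGCGATCTGGTATTTGCTCTATCTTCCTGC",
    "CTTAACTGCAAAAGTATCATACATATTTACTCTAGTGTTCGGCCGGATCCCCCCCTTATTGGGTCTGGAGCATACTTCCTTGGTATGCTGCTATCTTATTATTCAAATATTTCTCGTGGCCAAATGCCCGGATCTACAGGGGGGTCGGACAAAGGTCTTGCCACGAACAGGTCTAAAAACCCGTGGGTGTACCAGAGGAACGAACAGTTATCAGACCACATTGACTTCCATATGCCTATTGTGTATCACGTCTTGTTCATAGTATTTGGGGATGTTATGACTGCTTACTGT",
    "CTTAACTGCAAAAGTATGCTACATATTTACTTTAGTGCTCGGCCGGATCCCCCCATTATTGGGACTGGAGCTTACTTCCTTGGTGTACTGCTATCTAATGATTCAAATGTTTCACGTGGCCAAATGCCCGGATCTACAGGGGGGCCGGACAAAGGTCCTGACACCATCAGGTCTAAAAACCCCTCGGTGTCCCGGAGGAACGAAGAGTTATTAGACGAGATTGACTACCATATGCCTATTGTGTATCTCGTCTTGTTCATAGTATTTGGGGATGTTATGACTGCTTACTGC",
    "GTAAACACTACTATAGTGGAGTCAAACTTACAAGGTTGGGCTGTGATATCCCACGGCATATGGTCAAGCCTAGGAACTGTGTCTGACCTCCCCTGCATATCCCCAGAAGGTCGCTTAGTCCAAGATCAGTCATACAGGACGGGCGCCATCCTACGCTGCGGAGGGTGCCTAACCTTTAGAGAAGTGTTTATGGAATCGTGTATGATCGGATGGACGCGTCCACGTACGATAGTTCTTTCTCTAGATAGCCGTTTAACGAGCCAATCTCTCGTTTACACTCCGATCAATTGT",
    "GTAAACACTACTATAGTGGAGTCATACTTAAAAGCTTGGGCTGTGATATCCCACGGCATCTGGTCACCTCTAGGAACTGTGTCTGCCGTCCCCTGCAAATCCCCAGAAGGGCGCTTAGTCCAAGACCAGTCATTCAGGACGGGAGACATCCTACGCTGCGGAGGGTGCTTAACAAGTAGAGGTGTGTTTGTGGAATCGTGTATGATCGGATGGACGCGTCCACCTACGATAGTTCTATCTCTAGATAGGCGTTTAACGAGTCGATCTCTCGTTTACACTACGATCAATTGT",
    "CCTACGCCACTGAGTAACTATTTCAGTAGGAGCGTCAATACCCTCGAAGCACATCTACGGGAGAGGACGCACAGGTTGATCTGCATGGTGTCGTTCTCCGGGCTTGGTGAGCAGCCACCATTCGTCGATAACCTGAAGTGCCTAACCCGGGTAATTGTAGCTGGAAGGAGGTCGTCCCGTCCGTCTCTGGGCCTGACGACAGCCTACGGGTGGGTCTATAGTAAAGCGCGCTGCCTTTACCGTGCAAGACGTGGCATAGGTTCGGCATGCGCCAGATATAGCTCGACTTGT",
    "CCTACGCCACTCCGTAACCATTTCAGTAGGAGCGTCAACACCCTCGAAGCACATCTACCGGGGAGGACGCACAGGTTGATCTGCATGGTGTCGTTATCCGGGCTTGGTGAGCAGCCAGCATTCGTCGATAACCTGAAGTTCCTAACCCGGAGAATTGTAGCTGGAAGGAGGTCGTCCCGTACGTCTCTGGGCCTCACGACTCACTACGAGTGGTTTTGTAGTAAAGCGTGCAGCCATTACCCTGCAAGACTTGGCATAGGTTCGTCATGCGCCAGATATAGCTCGGCTTGT")
.toy_j_names <- c("IGHJ1*01", "IGHJ2*01", "IGHJ3*01", "IGHJ4*01")
.toy_j_seqs <- c(
    "GCCAGTTGGGGATACCTAACCCTGCGCCCTGTCTTTACAAACTCACAG",
    "AATCCTTGGGATTATGCAGGCATGGCGCGTCCAAACGGGCAATTCACG",
    "CGCGTATTCGGCAACGACTCGGGCATTGGACTCATTGTGAATCTAGAC",
    "GGACTGTGGATATGGAGCGTCAAAACTGCTATGCACCGACGCCTTTAT")
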