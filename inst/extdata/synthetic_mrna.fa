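>SYN001 synthetic hepcidin-like mRNA
CGGTCACACCAGGAGAAACTCGTAAAACTTCAAACATCACGTATGATTACAACTCCCATGAAAAGCCACCCCTCGCGACCTCATGAGGAGTTGGGGCTTAAATGGAGTCTATGCGAAAGCGCGCCTTATATGGGTATACGAATGAGGGCGACCATCGGGACTGTTGTTAACTGATACAAAATTTACTCCACTTTACTGACGGTTGACCCGCTGCTGCTTTAACCTCGACATGACGAAAGCCCGATACCTTTGCTAATATTTTTAACATGTAAGGTTTCACCGACAGTACACTGCAGTCATGTGCGCCAAGAGTCCTGTGCTGAGAATAGGTATTAGTCAGTCGATTAGACTGTCAAATAAACGTTCTATCTAGTCGTAAAAAAAAAAAAAA
>SYN002 synthetic partial mRNA
GAGACGTAGGTCCCTCGCCGTACCCACTGGCTAGTTCGCCAAAACATTATAGTAACATTAGTCTGCTCTGCACAAATCTTACCGGCGACGCGGGGAAACACTAAATATCCCCCATGACTCACGAGGAGCTGTCGAAGGCTATTCGGGATACTCAACCTTACGACGCTCCCACGCGGGTGA
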