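LOCUS       SYN001                   391 bp    mRNA    linear   SYN 01-JAN-2026
DEFINITION  synthetic hepcidin-like full-length mRNA (test fixture).
ACCESSION   SYN001
FEATURES             Location/Qualifiers
     source          1..391
                     /organism="synthetic construct"
     5'UTR           1..60
     CDS             61..300
                     /product="synthetic peptide"
     3'UTR           301..391
ORIGIN
        1 cggtcacacc aggagaaact cgtaaaactt caaacatcac gtatgattac aactcccatg
       61 aaaagccacc cctcgcgacc tcatgaggag ttggggctta aatggagtct atgcgaaagc
      121 gcgccttata tgggtatacg aatgagggcg accatcggga ctgttgttaa ctgatacaaa
      181 atttactcca ctttactgac ggttgacccg ctgctgcttt aacctcgaca tgacgaaagc
      241 ccgatacctt tgctaatatt tttaacatgt aaggtttcac cgacagtaca ctgcagtcat
      301 gtgcgccaag agtcctgtgc tgagaatagg tattagtcag tcgattagac tgtcaaataa
      361 acgttctatc tagtcgtaaa aaaaaaaaaa a
//
LOCUS       SYN002                   180 bp    mRNA    linear   SYN 01-JAN-2026
DEFINITION  synthetic partial mRNA without UTR annotation (test fixture).
ACCESSION   SYN002
FEATURES             Location/Qualifiers
     source          1..180
                     /organism="synthetic construct"
ORIGIN
        1 gagacgtagg tccctcgccg tacccactgg ctagttcgcc aaaacattat agtaacatta
       61 gtctgctctg cacaaatctt accggcgacg cggggaaaca ctaaatatcc cccatgactc
      121 acgaggagct gtcgaaggct attcgggata ctcaacctta cgacgctccc acgcgggtga
//
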