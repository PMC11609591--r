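9 dG = -1.20 hairpin
1 G 0 2 9 1
2 G 1 3 8 2
3 G 2 4 7 3
4 A 3 5 0 4
5 A 4 6 0 5
6 A 5 7 0 6
7 C 6 8 3 7
8 C 7 9 2 8
9 C 8 0 1 9
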