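>hairpin
GGGAAACCC
(((...))) (-1.20)
>openchain
AAAAAUUU
........ (0.00)
>twohelix
AAGCAAAGCAAGGGAAACCCAA
..((...))..(((...))).. (-2.10)
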