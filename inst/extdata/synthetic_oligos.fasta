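>a
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTA
>b
ACATAAGTGCAAGCTCAATCTACTCATATACACCACGA
>c
ATCTACAGTTCTCAGCAACGCAGGAGGATCGTCGGTCT
>d
TACCTGGTGAAGTAGTAATGATAGGATCTCACACTACA
>e
AATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATC
>f
CCTTAAGCCAATACGACCAATCTAAGGAACGGCCGTGA
>g
AAGGATCTCTGACTATCACAACCGTGAATGTCAGATGG
>h
CTCTTGTCTACTGTCTATTGACTGAGTGCTGCGCCTGC
>i
TGCGACCGTGACAGCGAGCGGACCTTATTGAAGTACGG
>j
CCACACTTACACCTAGCGCCATACACGCGGAAGCGTCG
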