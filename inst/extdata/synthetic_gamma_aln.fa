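>ref
GGAAACGGAGGAAACAGAAGAAAGAAACCACCCCCAAAAG
>relative1
GCAAAGGGAGGAAACAGACGAAAGAAACCACCCCCAAAAA
>relative2
GGAAACGAAGGAAACAGAAGCCAGAAACCACUCCCAAUAG
>relative3
GGAAACGAAGGAAACAGAAGAAAGGAUCCAGCCCCAAAAG
>relative4
GGGCACUGAGGAAACAGAAGAAAGAAACCACCAGCAAAAG
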