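# synthetic locked positions (with optional IUPAC column)
7 N
9
12
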