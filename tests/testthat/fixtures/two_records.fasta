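>contig_a first test record
ACGTACGTAC
GTACGT
>contig_b
TTTTGGGGCCCCAAAA
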