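>Contig1
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
ACGTACGTACGTACGT
>Contig2
TTGCATTGCATTGCATTGCATTGCATTGCATTGCATTGCATTGCATTGCA
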