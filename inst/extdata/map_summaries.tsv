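population	n_loci	length_cM
AM-DH	968	1870
DK-DH	800	1938
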