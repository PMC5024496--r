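trial	n_level	nni
LR09	N1	0.96
LR09	N2	1.31
LR10	N1	0.97
LR10	N2	1.17
Ch14	N1	0.81
Ch14	N2	1.08
Dij14	N1	0.81
Dij14	N2	0.93
Pre14	N1	0.67
Pre14	N2	1.02
LR11	N1	0.97
LR11	N2	0.93
LR13	N1	0.81
LR13	N2	1.12
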