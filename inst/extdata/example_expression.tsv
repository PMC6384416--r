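gene	logFC	SE
MUC5AC	1.8	0.25
MUC5B	1.2	0.30
SCGB1A1	-0.9	0.28
AREG	1.5	0.22
DUSP1	1.1	0.26
KRT5	0.1	0.31
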