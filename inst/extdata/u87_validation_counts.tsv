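method	tp	fp	fn	tn	n_predicted_total
DeepRed	47	1	12	132	167
Separate	49	36	10	97	NA
GIREMI	4	2	55	131	NA
RNAEditor	41	2	18	131	NA
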