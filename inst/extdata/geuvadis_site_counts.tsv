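method	n_total	n_a_to_i
DeepRed	100116	79172
GIREMI	93910	62222
Separate	146173	95986
Pooled	538467	372744
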