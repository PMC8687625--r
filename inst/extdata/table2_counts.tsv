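source	n_total	n_selected
CS	119	31
CX	189	18
DS	202	114
DG	125	8
HH	189	50
total	728	205
literature	36	36
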