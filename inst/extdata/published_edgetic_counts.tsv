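dataset	method	k_N	n_N	k_M	n_M
Y2H-SI	geometry	19	376	27	145
IntAct-SI	geometry	164	2394	140	908
experiment	experiment	2	47	62	197
Y2H-SI	physics	12	374	16	140
IntAct-SI	physics	103	2360	104	894
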