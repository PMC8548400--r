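protein_id	residue_index	score
P1	1	0.2
P1	2	0.4
P1	3	0.9
P2	1	0.5
P2	2	0.5
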