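Sequence	MS/MS Count	Experiment
ARLPLPKE	3	20S_1
SEQLQARL	11	20S_1
SEQLQARL	9	26S_2
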