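sample_id	condition	replicate	peptide	psm_count	branch_pos	branch_remnant
20S_r1	20S	1	ARLPLPKE	12	7	RGG
20S_r1	20S	1	SEQLQARL	30		
20S_r2	20S	2	SEQLQARL	22		
20S_r3	20S	3	SEQLQARL	25		
20S_r1	20S	1	VIDRRLPR	8		
20S_r2	20S	2	VIDRRLPR	5		
26S_r1	26S	1	SEQLQARL	14		
26S_r2	26S	2	SEQLQARL	11		
26S_r2	26S	2	MALRVTR	9		
26S_r3	26S	3	MALRVTR	7		
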