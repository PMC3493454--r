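run_id	condition	replicate
H2AZ_rep1	H2A.Z	1
H2AZ_rep2	H2A.Z	2
H2AZ_rep3	H2A.Z	3
H2A_rep1	H2A	1
H2A_rep2	H2A	2
H2A_rep3	H2A	3
GFP_rep1	GFP	1
GFP_rep2	GFP	2
GFP_rep3	GFP	3
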