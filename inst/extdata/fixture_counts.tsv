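group_id	representative	H2AZ_rep1	H2AZ_rep2	H2AZ_rep3	H2A_rep1	H2A_rep2	H2A_rep3	GFP_rep1	GFP_rep2	GFP_rep3
1	NUC001	20	18	22	10	9	11	1	1	1
2	NUC002	15	0	12	0	0	0	0	0	0
3	NUC003	30	28	35	60	55	50	2	3	1
4	NUC004	9	0	0	0	0	0	0	0	0
5	NUC005	4	5	6	0	0	0	2	2	2
6	NUC006	0	0	0	5	5	5	3	3	3
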