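characteristic	level	group	count	group_total	printed_pct
sex	F	Overall	42	96	44%
sex	F	NAT	9	19	47%
sex	F	TME	12	32	38%
sex	F	Tumour	21	45	47%
sex	M	Overall	54	96	56%
sex	M	NAT	10	19	53%
sex	M	TME	20	32	62%
sex	M	Tumour	24	45	53%
t_stage	0	Overall	19	96	20%
t_stage	0	NAT	19	19	100%
t_stage	0	TME	0	32	0%
t_stage	0	Tumour	0	45	0%
t_stage	1	Overall	24	96	25%
t_stage	1	TME	11	32	34%
t_stage	1	Tumour	13	45	29%
t_stage	2	Overall	34	96	35%
t_stage	2	TME	15	32	47%
t_stage	2	Tumour	19	45	42%
t_stage	3	Overall	12	96	12%
t_stage	3	TME	4	32	12%
t_stage	3	Tumour	8	45	18%
t_stage	4	Overall	7	96	7.3%
t_stage	4	TME	2	32	6.2%
t_stage	4	Tumour	5	45	11%
n_stage	0	Overall	78	96	81%
n_stage	0	NAT	19	19	100%
n_stage	0	TME	23	32	72%
n_stage	0	Tumour	36	45	80%
n_stage	1	Overall	13	96	14%
n_stage	1	TME	6	32	19%
n_stage	1	Tumour	7	45	16%
n_stage	2	Overall	3	96	3.1%
n_stage	2	TME	2	32	6.2%
n_stage	2	Tumour	1	45	2.2%
n_stage	3	Overall	2	96	2.1%
n_stage	3	TME	1	32	3.1%
n_stage	3	Tumour	1	45	2.2%
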