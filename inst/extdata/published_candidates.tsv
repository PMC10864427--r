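cell_line	gene	substitution	allele	mt_peptide	mt_ic50_nM	wt_peptide	wt_ic50_nM	printed_fold_change	nt_change
PC-B-142CA	ADGRL1	E274K	HLA-A*11:01	KTDIDLAVDK	38.970	KTDIDLAVDE	24602.85	631.32	G-A
PC-B-142CA	PARP1	E619K	HLA-A*11:01	AIEHFMKLYK	13.346	AIEHFMKLYE	2110.72	158.15	G-A
PC-B-142CA	SEC14L2	R43Q	HLA-A*11:01	LQARSFDLQK	118.433	LRARSFDLQK	3646.31	30.78	G-A
PC-B-148CA	LSR	I158F	HLA-A*24:02	YYQGRRFTI	10.190	YYQGRRITI	33.99	3.33	A-T
PC-B-148CA	ALKBH6	V83M	HLA-A*24:02	RYMDKVSNLSLF	8.182	RYVDKVSNLSLF	22.59	2.76	G-A
PC-B-148CA	GAA	I823T	HLA-C*07:02	LRAGYTIPL	61.563	LRAGYIIPL	88.89	1.44	T-C
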