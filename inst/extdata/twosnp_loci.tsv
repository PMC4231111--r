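locus	snp_id	chrom	bp	effect_allele	eaf	beta	se	pval	n	bJ	ld_r_next
BCL11A	rs2192512	2	59854224	C	0.475	0.058	0.014	6.50E-04	110517	0.060	-0.017
BCL11A	rs243019	2	60439310	C	0.451	0.086	0.014	2.70E-06	117602	0.087	0
ZMIZ1	rs3915932	10	80611942	G	0.592	0.095	0.018	4.70E-08	69629.2	0.098	-0.040
ZMIZ1	rs6480947	10	80906216	G	0.156	0.113	0.027	2.20E-04	59743.8	0.119	0
KCNJ11	rs7928810	11	17329019	C	0.396	0.068	0.014	1.30E-04	117423	0.068	-0.004
KCNJ11	rs757984	11	17576484	T	0.803	0.077	0.019	4.90E-04	102511	0.077	0
MTNR1B	rs10830962	11	92338075	G	0.408	0.104	0.014	1.50E-08	124966	0.101	0.069
MTNR1B	rs531573	11	92444531	C	0.182	0.086	0.018	1.70E-04	111150	0.077	0
C2CD4A	rs6494307	15	60181982	C	0.572	0.077	0.014	1.80E-05	116797	0.077	-0.001
C2CD4A	rs2456936	15	60502334	C	0.785	0.077	0.019	1.10E-03	96195.2	0.077	0
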