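snp	chr	bp	effect_allele	other_allele	eaf	beta	se	pvalue
rs6700896	1	65862370	T	C	0.38	-0.00995	0.01493	0.41
rs4537545	1	152685503	T	C	0.43	-0.01980	0.00991	0.21
rs7553007	1	157965173	A	G	0.33	-0.01980	0.01479	0.14
rs1183910	12	119905190	T	C	0.32	0.02956	0.00981	0.059
rs4420638	19	50114786	G	A	0.19	-0.11333	0.02228	2.0e-7
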