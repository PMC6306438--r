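snp	chr	bp	effect_allele	other_allele	eaf	beta	se	pvalue
rs6700896	1	65862370	T	C	0.38	-0.147	0.01429	1.6e-21
rs4537545	1	152685503	T	C	0.43	-0.108	0.01531	5.1e-11
rs7553007	1	157965173	A	G	0.33	-0.207	0.01429	3.3e-38
rs1183910	12	119905190	T	C	0.32	-0.136	0.01429	1.2e-17
rs4420638	19	50114786	G	A	0.19	-0.218	0.01837	2.1e-25
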