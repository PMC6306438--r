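snp	chr	bp	effect_allele	other_allele	eaf	beta_exposure	se_exposure	p_exposure	beta_outcome	se_outcome	p_outcome
rs6700896	1	65862370	T	C	0.38	-0.147	0.01429	1.6e-21	-0.029	0.026	0.2646856
rs7553007	1	157965173	A	G	0.33	-0.207	0.01429	3.3e-38	0.037	0.026	0.1547139
rs1183910	12	119905190	T	C	0.32	-0.136	0.01429	1.2e-17	-0.037	0.027	0.17057
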