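Deafness	OMIM disease genes	DFNA5	MYH14	ACTG1	MYH9	RDX
Anemia	OMIM disease genes	TPI1	HK1	GSS	GPI
Myopathy	OMIM disease genes	TPM2	TPM3	FLNC
Leukemia	OMIM disease genes	LPP	NUMA1	PML
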