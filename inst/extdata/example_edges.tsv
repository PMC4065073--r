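# toy actin-myosin interaction neighbourhood (illustrative edges only)
MYH9	ACTG1
MYH9	MYH10
MYH9	MYH14
MYH9	MYL12B
MYH10	MYL12B
MYH14	MYL12B
ACTG1	TPM2
ACTG1	TPM3
ACTG1	FLNC
TPM2	TPM3
RDX	ACTG1
RDX	MSN
MSN	EZR
EZR	RDX
TPI1	GPI
TPI1	HK1
GPI	HK1
GSS	GPI
PML	NUMA1
LPP	PML
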