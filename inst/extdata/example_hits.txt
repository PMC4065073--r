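# toy hit list (mixed murine/human casing on purpose)
Myh9
MYH10
Myh14
MYL12B
ACTG1
Rdx
MSN
TPM2
TPI1
GPI
HK1
PML
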