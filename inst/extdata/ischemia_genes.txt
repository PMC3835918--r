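JNK3
JUNB
AP1B1
AP1S1
AP1M1
AP1S1
CA-IX
HHR6B
PRSS25
FOS
HIF1A
HO-1
JUND
JUN
KRT19
KRT20
CEA
KLF6
MDM4
FBLN2
FGRF4
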