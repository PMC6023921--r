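# Non-IAHC exclusion markers for in silico purification:
# mesenchymal, EMP-like and sub-aortic-patch contaminant genes.
Epha7
Crabp1
Cxcl12
Pdgfrb
Sox11
Ptprd
Col3a1
Csf1r
Fcgr3
Gata3
Cdkn1c
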