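# Synthetic stand-in for a genome-wide mouse transcription factor list.
# Covers the 36 temporal-archetype TFs emitted by the simulator plus a few
# factors that are typically absent from aortic data (exercises the
# absent-TF warning path).  Replace with a full curated TF list for real data.
Sox17
Hey2
Elk3
Jun
Mecom
Epas1
Id3
Erg
Sox7
Hes1
Foxc2
Tcf15
Gfi1
Ikzf2
Dnmt3a
Lmo2
Tal1
Lyl1
Cbfb
Etv6
Meis1
Mycn
Myb
Nfe2
Zfpm1
Klf1
Gata1
Cebpa
Irf8
Sfpi1
Hhex
Nfia
Bcl11a
Ikzf1
Stat5a
Cited4
Pou5f1
Nanog
Cdx2
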