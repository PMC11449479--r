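name,formula
GlcNAc,C8H15NO6
MurNAc,C11H19NO8
Ala,C3H7NO2
iGlu,C5H9NO4
DAP,C7H14N2O4
Lys,C6H14N2O2
Arg,C6H14N4O2
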