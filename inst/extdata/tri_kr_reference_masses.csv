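fragment,quantity,nn,no,on,oo
GlcNAc-MurNAc(r)-Ala-iGlu-DAP->Lys-Arg,calculated,1154.57,1172.59,1194.66,1212.69
GlcNAc-MurNAc(r)-Ala-iGlu-DAP->Lys-Arg,observed,1154.56,1172.58,1194.65,1212.68
MurNAc(r)-Ala-iGlu-DAP->Lys-Arg,calculated,951.49,969.51,982.56,1000.58
MurNAc(r)-Ala-iGlu-DAP->Lys-Arg,observed,951.49,969.52,982.56,1000.58
Ala-iGlu-DAP->Lys-Arg,calculated,674.37,692.39,693.41,711.43
Ala-iGlu-DAP->Lys-Arg,observed,674.38,692.39,693.41,711.43
iGlu-DAP->Lys-Arg,calculated,603.33,621.36,618.37,636.39
iGlu-DAP->Lys-Arg,observed,603.34,621.37,618.36,636.39
DAP->Lys-Arg,calculated,474.29,492.31,483.31,501.33
DAP->Lys-Arg,observed,474.29,492.31,483.31,501.33
Lys-Arg,calculated,302.21,320.23,302.21,320.23
Lys-Arg,observed,302.21,320.23,302.21,320.23
Arg,calculated,174.11,184.12,174.11,184.12
Arg,observed,174.11,184.12,174.11,184.12
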