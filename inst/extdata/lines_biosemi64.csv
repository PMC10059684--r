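line_id,hemisphere,pair_id,e1,e2,e3,e4,e5,e6,e7
mid,mid,NA,Oz,POz,Pz,CPz,Cz,FCz,Fz
L1,left,P1,O1,PO3,P1,CP1,C1,FC1,F1
R1,right,P1,O2,PO4,P2,CP2,C2,FC2,F2
L2,left,P2,O1,PO3,P3,CP3,C3,FC3,F3
R2,right,P2,O2,PO4,P4,CP4,C4,FC4,F4
L3,left,P3,O1,PO7,P5,CP5,C5,FC5,F5
R3,right,P3,O2,PO8,P6,CP6,C6,FC6,F6
L4,left,P4,O1,PO7,P7,TP7,T7,FT7,F7
R4,right,P4,O2,PO8,P8,TP8,T8,FT8,F8
L5,left,P5,O1,PO7,P9,TP7,T7,FT7,AF7
R5,right,P5,O2,PO8,P10,TP8,T8,FT8,AF8
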