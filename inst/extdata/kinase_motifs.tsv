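motif	kinase
[LM]xx[ST]*x[STVILMFYW][YIFM]	Atg1
[ST]*x[RK]	Cdc15
[ST]*P	Cdc28 minimal
[ST]*Px[KR]	Cdc28 strict
[DEN]x[ST]*	Cdc5
[ST]*[DEST]	Cdc7/Cka1
[ST]xx[ST]*	Hrr25
RPx[ST]*	Ime2
[RK]x[ST]*	Ipl1/PKA
[ST]*Q	Mec1
[RK]xx[ST]*	Mek1/Sgk2
[DER]x[ST]*	Mps1
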