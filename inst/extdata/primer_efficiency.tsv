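gene	r_squared	efficiency_pct
ACT	0.997	96.014
CYP	0.990	100.106
EF1a	0.999	97.624
EIF	0.999	99.905
Fbox	0.997	96.744
FLD	0.997	94.312
GAPDH	0.998	95.161
HIS	0.999	96.045
PP2A	0.992	98.785
RP	0.996	95.203
SAND	0.993	97.808
TBP	0.991	103.908
TUB	0.995	100.983
UBCE	0.990	101.35
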