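indicator,Ej,Dj,Wj_percent
OH,0.88,0.12,7.41
ABTS,0.84,0.16,9.46
DPPH,0.90,0.10,5.76
FRAP,0.79,0.21,12.43
FICC,0.71,0.29,17.29
O2,0.86,0.14,8.41
EPS,0.83,0.17,10.35
LacticAcid,0.86,0.14,8.46
AntiSaureus,0.81,0.19,11.33
AntiEcoli,0.85,0.15,9.12
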