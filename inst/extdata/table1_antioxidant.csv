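strain,OH,OH_sd,ABTS,ABTS_sd,DPPH,DPPH_sd,O2,O2_sd,FICC,FICC_sd,FRAP,FRAP_sd
Lac. lactis W3A,92.69,0.96,98.67,0.75,44.78,1.43,15.99,1.17,28.49,1.17,65.11,0.76
S. lutetiensis W3B,95.26,0.38,96.43,0.14,46.26,0.60,17.24,1.23,25.15,0.95,35.56,1.42
Lac. lactis W3C,87.56,0.22,95.86,0.30,51.76,0.38,11.88,1.27,54.70,1.24,266.83,1.57
E. durans W3D,86.06,0.09,96.81,0.29,50.64,1.35,20.26,1.40,25.78,1.16,273.14,1.36
Leu. mesenteroides W3E,93.94,0.19,98.09,0.53,37.72,0.58,24.41,1.33,23.98,1.10,98.66,0.17
E. durans W3F,93.05,0.03,96.67,0.34,53.13,0.36,31.30,0.41,38.81,1.60,79.53,0.03
Leu. lactis W3J,94.44,0.08,96.94,0.65,52.13,1.45,22.00,1.06,39.44,1.38,141.53,0.62
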