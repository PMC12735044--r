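strain,d_plus,d_minus,ci,rank
Lac. lactis W3A,0.592,0.478,0.447,4
S. lutetiensis W3B,0.682,0.44,0.392,6
Lac. lactis W3C,0.662,0.58,0.467,3
E. durans W3D,0.619,0.444,0.417,5
Leu. mesenteroides W3E,0.706,0.361,0.338,7
E. durans W3F,0.496,0.558,0.53,2
Leu. lactis W3J,0.406,0.597,0.595,1
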