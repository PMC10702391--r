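mutant,ligand,ddg_kcal_mol
V247F,L-aspartate,0.52
V247F,L-glutamate,0.08
V247F,TFB-TBOA,-0.70
V247F,UCPH-101,0.68
P392L,L-aspartate,0.04
P392L,L-glutamate,-0.01
P392L,TFB-TBOA,-0.70
A446E,L-aspartate,6.39
A446E,L-glutamate,-0.90
A446E,TFB-TBOA,1.86
A446V,L-aspartate,0.58
A446V,L-glutamate,-1.73
A446V,TFB-TBOA,2.23
L448Q,L-aspartate,-0.35
L448Q,L-glutamate,-1.88
L448Q,TFB-TBOA,1.79
R479W,L-aspartate,7.13
R479W,L-glutamate,6.42
R479W,TFB-TBOA,42.19
Y127C,UCPH-101,5.82
C252F,UCPH-101,-0.49
R388K,UCPH-101,-0.05
F389L,UCPH-101,3.83
V390M,UCPH-101,-0.76
I397V,UCPH-101,-0.62
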