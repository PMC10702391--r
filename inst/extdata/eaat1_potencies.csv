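mutant,compound,measure,value,sem,emax_pct,emax_sem,flag
WT,L-glutamate,pEC50,3.5,0.0,117,5,ok
WT,L-aspartate,pEC50,3.6,0.1,108,9,ok
WT,TFB-TBOA,pIC50,6.7,0.1,,,ok
WT,UCPH-101,pIC50,5.4,0.0,,,ok
Y127C,L-glutamate,pEC50,4.1,0.1,23,3,ok
Y127C,L-aspartate,pEC50,,,,,bell_shaped
Y127C,TFB-TBOA,pIC50,6.2,0.0,,,ok
Y127C,UCPH-101,pIC50,,,,,not_determined
M128R,L-glutamate,pEC50,,,,,not_determined
M128R,L-aspartate,pEC50,,,,,not_determined
M128R,TFB-TBOA,pIC50,,,,,not_determined
M128R,UCPH-101,pIC50,,,,,not_determined
V247F,L-glutamate,pEC50,3.8,0.0,55,9,ok
V247F,L-aspartate,pEC50,3.8,0.0,49,1,ok
V247F,TFB-TBOA,pIC50,5.7,0.1,,,ok
V247F,UCPH-101,pIC50,5.3,0.0,,,ok
T318A,L-glutamate,pEC50,3.3,0.0,156,4,ok
T318A,L-aspartate,pEC50,3.5,0.0,158,18,ok
T318A,TFB-TBOA,pIC50,6.9,0.1,,,ok
T318A,UCPH-101,pIC50,5.4,0.0,,,ok
V390M,L-glutamate,pEC50,3.5,0.0,132,6,ok
V390M,L-aspartate,pEC50,3.6,0.0,112,3,ok
V390M,TFB-TBOA,pIC50,6.7,0.0,,,ok
V390M,UCPH-101,pIC50,5.4,0.0,,,ok
P392L,L-glutamate,pEC50,3.8,0.0,71,4,ok
P392L,L-aspartate,pEC50,3.9,0.0,46,3,ok
P392L,TFB-TBOA,pIC50,6.5,0.1,,,ok
P392L,UCPH-101,pIC50,,,,,not_determined
A446E,L-glutamate,pEC50,4.4,0.3,8,2,ok
A446E,L-aspartate,pEC50,,,,,bell_shaped
A446E,TFB-TBOA,pIC50,7.4,0.2,,,ok
A446E,UCPH-101,pIC50,5.9,0.2,,,ok
A446V,L-glutamate,pEC50,4.3,0.2,16,4,ok
A446V,L-aspartate,pEC50,,,,,bell_shaped
A446V,TFB-TBOA,pIC50,,,,,not_determined
A446V,UCPH-101,pIC50,,,,,not_determined
L448Q,L-glutamate,pEC50,3.3,0.1,116,25,ok
L448Q,L-aspartate,pEC50,3.7,0.1,47,13,ok
L448Q,TFB-TBOA,pIC50,7.9,0.0,,,ok
L448Q,UCPH-101,pIC50,5.9,0.1,,,ok
R479W,L-glutamate,pEC50,,,,,not_determined
R479W,L-aspartate,pEC50,,,,,not_determined
R479W,TFB-TBOA,pIC50,,,,,not_determined
R479W,UCPH-101,pIC50,,,,,not_determined
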