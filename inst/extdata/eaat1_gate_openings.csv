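system,mean_A,sd_A
WT,6.0,0.2
Y127C,6.6,0.7
M128R,5.2,0.1
P392L,7.0,0.2
A446E,5.4,0.2
A446V,5.4,0.1
L448Q,5.6,0.2
R479W,10.5,0.1
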