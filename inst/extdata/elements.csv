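element,vdw_radius,lj_rmin2,lj_eps
H,1.20,0.600,0.0157
C,1.70,1.908,0.0860
N,1.55,1.824,0.1700
O,1.52,1.661,0.2100
S,1.80,2.000,0.2500
P,1.80,2.100,0.2000
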