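res,atom,a3,a2,a1,length_A,angle_deg,torsion_deg
ALA,CB,C,N,CA,1.5294,109.464,-119.999
ARG,CB,C,N,CA,1.5363,111.55,-123.561
ARG,CG,N,CA,CB,1.5371,114.536,63.801
ARG,CD,CA,CB,CG,1.5273,112.417,177.631
ARG,NE,CB,CG,CD,1.4435,111.016,60.183
ARG,CZ,CG,CD,NE,1.4058,123.005,179.976
ARG,NH1,CD,NE,CZ,1.3906,120.996,179.986
ARG,NH2,CD,NE,CZ,1.3912,119.815,-0.012
ASN,CB,C,N,CA,1.5309,109.454,-119.996
ASN,CG,N,CA,CB,1.5066,109.484,-64.948
ASN,ND2,CA,CB,CG,1.3476,120.012,-179.982
ASN,OD1,CA,CB,CG,1.2133,119.974,-0.055
ASP,CB,C,N,CA,1.5301,109.48,-120.011
ASP,CG,N,CA,CB,1.5075,109.463,-64.988
ASP,OD1,CA,CB,CG,1.208,119.959,-0.061
ASP,OD2,CA,CB,CG,1.3415,119.999,-179.997
CYS,CB,C,N,CA,1.5285,109.496,-120.014
CYS,SG,N,CA,CB,1.8141,109.498,-59.998
GLN,CB,C,N,CA,1.5288,109.459,-120.066
GLN,CG,N,CA,CB,1.5284,109.534,-59.924
GLN,CD,CA,CB,CG,1.5066,109.543,-179.992
GLN,NE2,CB,CG,CD,1.3471,120.093,179.988
GLN,OE1,CB,CG,CD,1.2122,119.937,-0.055
GLU,CB,C,N,CA,1.5302,109.482,-119.956
GLU,CG,N,CA,CB,1.5306,109.402,-65.014
GLU,CD,CA,CB,CG,1.5076,109.43,-179.998
GLU,OE1,CB,CG,CD,1.2084,120.003,-0.033
GLU,OE2,CB,CG,CD,1.3425,119.998,-179.97
HIS,CB,C,N,CA,1.5337,111.125,-122.779
HIS,CG,N,CA,CB,1.51,112.979,-158.204
HIS,CD2,CA,CB,CG,1.3376,129.928,89.836
HIS,ND1,CA,CB,CG,1.3513,120.329,-90.01
HIS,NE2,CB,CG,CD2,1.3739,105.332,-179.864
HIS,CE1,CB,CG,ND1,1.3369,107.862,179.905
ILE,CB,C,N,CA,1.5288,109.43,-120.073
ILE,CG1,N,CA,CB,1.5294,109.547,-59.994
ILE,CG2,N,CA,CB,1.5303,109.458,-179.966
ILE,CD1,CA,CB,CG1,1.5288,109.547,-180.0
LEU,CB,C,N,CA,1.5286,109.416,-119.973
LEU,CG,N,CA,CB,1.5303,109.495,-60.068
LEU,CD1,CA,CB,CG,1.53,109.5,179.985
LEU,CD2,CA,CB,CG,1.5285,109.501,-59.923
LYS,CB,C,N,CA,1.53,109.453,-119.967
LYS,CG,N,CA,CB,1.5307,109.418,-65.021
LYS,CD,CA,CB,CG,1.5308,109.441,180.0
LYS,CE,CB,CG,CD,1.5291,109.465,179.998
LYS,NZ,CG,CD,CE,1.4694,109.5,-179.951
MET,CB,C,N,CA,1.5294,109.427,-120.037
MET,CG,N,CA,CB,1.5284,109.545,-60.017
MET,SD,CA,CB,CG,1.8137,109.506,-179.985
MET,CE,CB,CG,SD,1.8135,100.034,-179.995
PHE,CB,C,N,CA,1.5289,109.474,-120.094
PHE,CG,N,CA,CB,1.5052,109.517,-59.932
PHE,CD1,CA,CB,CG,1.3817,120.058,89.968
PHE,CD2,CA,CB,CG,1.3832,120.005,-90.275
PHE,CE1,CB,CG,CD1,1.382,120.029,179.994
PHE,CE2,CB,CG,CD2,1.3819,119.977,179.839
PHE,CZ,CG,CD1,CE1,1.3806,120.047,-0.048
PRO,CB,C,N,CA,1.5434,104.722,-118.841
PRO,CG,N,CA,CB,1.5426,105.059,-23.8
PRO,CD,CA,CB,CG,1.5437,105.063,0.025
SER,CB,C,N,CA,1.5287,109.471,-120.02
SER,OG,N,CA,CB,1.4283,109.512,-59.969
THR,CB,C,N,CA,1.529,109.412,-120.0
THR,CG2,N,CA,CB,1.5301,109.525,-60.009
THR,OG1,N,CA,CB,1.428,109.505,60.022
TRP,CB,C,N,CA,1.5286,109.523,-120.026
TRP,CG,N,CA,CB,1.5067,109.442,-60.001
TRP,CD1,CA,CB,CG,1.3426,126.496,90.038
TRP,CD2,CA,CB,CG,1.4639,126.512,-90.341
TRP,NE1,CB,CG,CD1,1.3686,109.932,179.944
TRP,CE2,CB,CG,CD2,1.4068,106.076,179.958
TRP,CE3,CB,CG,CD2,1.3961,134.047,0.784
TRP,CZ2,CG,CD2,CE2,1.3906,119.346,-179.825
TRP,CZ3,CG,CD2,CE3,1.3659,119.795,179.639
TRP,CH2,CD2,CE2,CZ2,1.3773,119.806,0.221
TYR,CB,C,N,CA,1.5287,109.47,-120.041
TYR,CG,N,CA,CB,1.5062,109.497,-59.981
TYR,CD1,CA,CB,CG,1.3823,119.947,90.03
TYR,CD2,CA,CB,CG,1.383,119.943,-90.278
TYR,CE1,CB,CG,CD1,1.381,120.073,-179.976
TYR,CE2,CB,CG,CD2,1.3809,120.02,179.775
TYR,CZ,CG,CD1,CE1,1.3867,119.978,-0.102
TYR,OH,CD1,CE1,CZ,1.3582,120.13,-179.966
VAL,CB,C,N,CA,1.5287,109.445,-120.004
VAL,CG1,N,CA,CB,1.5299,109.509,-59.994
VAL,CG2,N,CA,CB,1.5292,109.49,60.032
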