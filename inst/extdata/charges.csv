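res,atom,charge
ALA,N,-0.145
ALA,CA,0.116
ALA,C,0.597
ALA,O,-0.568
ALA,CB,0.000
ARG,N,-0.145
ARG,CA,0.116
ARG,C,0.597
ARG,O,-0.568
ARG,CB,0.000
ARG,CG,0.050
ARG,CD,0.200
ARG,NE,-0.150
ARG,CZ,0.650
ARG,NH1,0.125
ARG,NH2,0.125
ASN,N,-0.145
ASN,CA,0.116
ASN,C,0.597
ASN,O,-0.568
ASN,CB,-0.020
ASN,CG,0.710
ASN,OD1,-0.590
ASN,ND2,-0.100
ASP,N,-0.145
ASP,CA,0.116
ASP,C,0.597
ASP,O,-0.568
ASP,CB,-0.200
ASP,CG,0.800
ASP,OD1,-0.800
ASP,OD2,-0.800
CYS,N,-0.145
CYS,CA,0.116
CYS,C,0.597
CYS,O,-0.568
CYS,CB,0.150
CYS,SG,-0.150
GLN,N,-0.145
GLN,CA,0.116
GLN,C,0.597
GLN,O,-0.568
GLN,CB,0.000
GLN,CG,-0.020
GLN,CD,0.710
GLN,OE1,-0.590
GLN,NE2,-0.100
GLU,N,-0.145
GLU,CA,0.116
GLU,C,0.597
GLU,O,-0.568
GLU,CB,0.000
GLU,CG,-0.200
GLU,CD,0.800
GLU,OE1,-0.800
GLU,OE2,-0.800
GLY,N,-0.145
GLY,CA,0.116
GLY,C,0.597
GLY,O,-0.568
HIS,N,-0.145
HIS,CA,0.116
HIS,C,0.597
HIS,O,-0.568
HIS,CB,0.000
HIS,CG,0.180
HIS,ND1,-0.380
HIS,CD2,-0.100
HIS,CE1,0.250
HIS,NE2,0.050
ILE,N,-0.145
ILE,CA,0.116
ILE,C,0.597
ILE,O,-0.568
ILE,CB,0.100
ILE,CG1,0.000
ILE,CG2,-0.050
ILE,CD1,-0.050
LEU,N,-0.145
LEU,CA,0.116
LEU,C,0.597
LEU,O,-0.568
LEU,CB,0.000
LEU,CG,0.100
LEU,CD1,-0.050
LEU,CD2,-0.050
LYS,N,-0.145
LYS,CA,0.116
LYS,C,0.597
LYS,O,-0.568
LYS,CB,0.000
LYS,CG,0.020
LYS,CD,0.100
LYS,CE,0.300
LYS,NZ,0.580
MET,N,-0.145
MET,CA,0.116
MET,C,0.597
MET,O,-0.568
MET,CB,0.050
MET,CG,0.030
MET,SD,-0.090
MET,CE,0.010
PHE,N,-0.145
PHE,CA,0.116
PHE,C,0.597
PHE,O,-0.568
PHE,CB,0.000
PHE,CG,0.010
PHE,CD1,0.000
PHE,CD2,0.000
PHE,CE1,0.000
PHE,CE2,0.000
PHE,CZ,-0.010
PRO,N,-0.266
PRO,CA,0.112
PRO,C,0.597
PRO,O,-0.568
PRO,CB,0.035
PRO,CG,0.010
PRO,CD,0.080
SER,N,-0.145
SER,CA,0.116
SER,C,0.597
SER,O,-0.568
SER,CB,0.230
SER,OG,-0.230
THR,N,-0.145
THR,CA,0.116
THR,C,0.597
THR,O,-0.568
THR,CB,0.270
THR,OG1,-0.250
THR,CG2,-0.020
TRP,N,-0.145
TRP,CA,0.116
TRP,C,0.597
TRP,O,-0.568
TRP,CB,0.000
TRP,CG,-0.100
TRP,CD1,0.100
TRP,CD2,0.100
TRP,NE1,-0.150
TRP,CE2,0.150
TRP,CE3,-0.100
TRP,CZ2,-0.050
TRP,CZ3,-0.050
TRP,CH2,0.100
TYR,N,-0.145
TYR,CA,0.116
TYR,C,0.597
TYR,O,-0.568
TYR,CB,0.000
TYR,CG,-0.030
TYR,CD1,0.020
TYR,CD2,0.020
TYR,CE1,-0.080
TYR,CE2,-0.080
TYR,CZ,0.430
TYR,OH,-0.280
VAL,N,-0.145
VAL,CA,0.116
VAL,C,0.597
VAL,O,-0.568
VAL,CB,0.100
VAL,CG1,-0.050
VAL,CG2,-0.050
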