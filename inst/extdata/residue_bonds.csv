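res,atom1,atom2
ALA,CA,N
ALA,C,CA
ALA,CA,CB
ALA,C,O
ARG,CA,N
ARG,C,CA
ARG,CA,CB
ARG,C,O
ARG,CB,CG
ARG,CD,CG
ARG,CD,NE
ARG,CZ,NE
ARG,CZ,NH1
ARG,CZ,NH2
ASN,CA,N
ASN,C,CA
ASN,CA,CB
ASN,C,O
ASN,CB,CG
ASN,CG,OD1
ASN,CG,ND2
ASP,CA,N
ASP,C,CA
ASP,CA,CB
ASP,C,O
ASP,CB,CG
ASP,CG,OD1
ASP,CG,OD2
CYS,CA,N
CYS,C,CA
CYS,CA,CB
CYS,C,O
CYS,CB,SG
GLN,CA,N
GLN,C,CA
GLN,CA,CB
GLN,C,O
GLN,CB,CG
GLN,CD,CG
GLN,CD,OE1
GLN,CD,NE2
GLU,CA,N
GLU,C,CA
GLU,CA,CB
GLU,C,O
GLU,CB,CG
GLU,CD,CG
GLU,CD,OE1
GLU,CD,OE2
GLY,CA,N
GLY,C,CA
GLY,C,O
HIS,CA,N
HIS,C,CA
HIS,CA,CB
HIS,C,O
HIS,CB,CG
HIS,CG,ND1
HIS,CD2,CG
HIS,CE1,ND1
HIS,CD2,NE2
HIS,CE1,NE2
ILE,CA,N
ILE,C,CA
ILE,CA,CB
ILE,C,O
ILE,CB,CG1
ILE,CB,CG2
ILE,CD1,CG1
LEU,CA,N
LEU,C,CA
LEU,CA,CB
LEU,C,O
LEU,CB,CG
LEU,CD1,CG
LEU,CD2,CG
LYS,CA,N
LYS,C,CA
LYS,CA,CB
LYS,C,O
LYS,CB,CG
LYS,CD,CG
LYS,CD,CE
LYS,CE,NZ
MET,CA,N
MET,C,CA
MET,CA,CB
MET,C,O
MET,CB,CG
MET,CG,SD
MET,CE,SD
PHE,CA,N
PHE,C,CA
PHE,CA,CB
PHE,C,O
PHE,CB,CG
PHE,CD1,CG
PHE,CD2,CG
PHE,CD1,CE1
PHE,CD2,CE2
PHE,CE1,CZ
PHE,CE2,CZ
PRO,CA,N
PRO,CD,N
PRO,C,CA
PRO,CA,CB
PRO,C,O
PRO,CB,CG
PRO,CD,CG
SER,CA,N
SER,C,CA
SER,CA,CB
SER,C,O
SER,CB,OG
THR,CA,N
THR,C,CA
THR,CA,CB
THR,C,O
THR,CB,OG1
THR,CB,CG2
TRP,CA,N
TRP,C,CA
TRP,CA,CB
TRP,C,O
TRP,CB,CG
TRP,CD1,CG
TRP,CD2,CG
TRP,CD1,NE1
TRP,CD2,CE2
TRP,CD2,CE3
TRP,CE2,NE1
TRP,CE2,CZ2
TRP,CE3,CZ3
TRP,CH2,CZ2
TRP,CH2,CZ3
TYR,CA,N
TYR,C,CA
TYR,CA,CB
TYR,C,O
TYR,CB,CG
TYR,CD1,CG
TYR,CD2,CG
TYR,CD1,CE1
TYR,CD2,CE2
TYR,CE1,CZ
TYR,CE2,CZ
TYR,CZ,OH
VAL,CA,N
VAL,C,CA
VAL,CA,CB
VAL,C,O
VAL,CB,CG1
VAL,CB,CG2
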