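residue,atom,charge
ALA,N,-0.470
ALA,HN,0.310
ALA,CA,0.070
ALA,HA,0.090
ALA,C,0.510
ALA,O,-0.510
ARG,N,-0.470
ARG,HN,0.310
ARG,CA,0.070
ARG,HA,0.090
ARG,C,0.510
ARG,O,-0.510
ASN,N,-0.470
ASN,HN,0.310
ASN,CA,0.070
ASN,HA,0.090
ASN,C,0.510
ASN,O,-0.510
ASP,N,-0.470
ASP,HN,0.310
ASP,CA,0.070
ASP,HA,0.090
ASP,C,0.510
ASP,O,-0.510
CYS,N,-0.470
CYS,HN,0.310
CYS,CA,0.070
CYS,HA,0.090
CYS,C,0.510
CYS,O,-0.510
GLN,N,-0.470
GLN,HN,0.310
GLN,CA,0.070
GLN,HA,0.090
GLN,C,0.510
GLN,O,-0.510
GLU,N,-0.470
GLU,HN,0.310
GLU,CA,0.070
GLU,HA,0.090
GLU,C,0.510
GLU,O,-0.510
HIS,N,-0.470
HIS,HN,0.310
HIS,CA,0.070
HIS,HA,0.090
HIS,C,0.510
HIS,O,-0.510
ILE,N,-0.470
ILE,HN,0.310
ILE,CA,0.070
ILE,HA,0.090
ILE,C,0.510
ILE,O,-0.510
LEU,N,-0.470
LEU,HN,0.310
LEU,CA,0.070
LEU,HA,0.090
LEU,C,0.510
LEU,O,-0.510
LYS,N,-0.470
LYS,HN,0.310
LYS,CA,0.070
LYS,HA,0.090
LYS,C,0.510
LYS,O,-0.510
MET,N,-0.470
MET,HN,0.310
MET,CA,0.070
MET,HA,0.090
MET,C,0.510
MET,O,-0.510
PHE,N,-0.470
PHE,HN,0.310
PHE,CA,0.070
PHE,HA,0.090
PHE,C,0.510
PHE,O,-0.510
SER,N,-0.470
SER,HN,0.310
SER,CA,0.070
SER,HA,0.090
SER,C,0.510
SER,O,-0.510
THR,N,-0.470
THR,HN,0.310
THR,CA,0.070
THR,HA,0.090
THR,C,0.510
THR,O,-0.510
TRP,N,-0.470
TRP,HN,0.310
TRP,CA,0.070
TRP,HA,0.090
TRP,C,0.510
TRP,O,-0.510
TYR,N,-0.470
TYR,HN,0.310
TYR,CA,0.070
TYR,HA,0.090
TYR,C,0.510
TYR,O,-0.510
VAL,N,-0.470
VAL,HN,0.310
VAL,CA,0.070
VAL,HA,0.090
VAL,C,0.510
VAL,O,-0.510
GLY,N,-0.470
GLY,HN,0.310
GLY,CA,-0.020
GLY,HA2,0.090
GLY,HA3,0.090
GLY,C,0.510
GLY,O,-0.510
PRO,N,-0.290
PRO,CA,0.020
PRO,HA,0.090
PRO,C,0.510
PRO,O,-0.510
PRO,CB,-0.180
PRO,HB2,0.090
PRO,HB3,0.090
PRO,CG,-0.180
PRO,HG2,0.090
PRO,HG3,0.090
PRO,CD,0.000
PRO,HD2,0.090
PRO,HD3,0.090
ALA,CB,-0.270
ALA,HB1,0.090
ALA,HB2,0.090
ALA,HB3,0.090
VAL,CB,-0.090
VAL,HB,0.090
VAL,CG1,-0.270
VAL,HG11,0.090
VAL,HG12,0.090
VAL,HG13,0.090
VAL,CG2,-0.270
VAL,HG21,0.090
VAL,HG22,0.090
VAL,HG23,0.090
LEU,CB,-0.180
LEU,HB2,0.090
LEU,HB3,0.090
LEU,CG,-0.090
LEU,HG,0.090
LEU,CD1,-0.270
LEU,HD11,0.090
LEU,HD12,0.090
LEU,HD13,0.090
LEU,CD2,-0.270
LEU,HD21,0.090
LEU,HD22,0.090
LEU,HD23,0.090
ILE,CB,-0.090
ILE,HB,0.090
ILE,CG1,-0.180
ILE,HG12,0.090
ILE,HG13,0.090
ILE,CG2,-0.270
ILE,HG21,0.090
ILE,HG22,0.090
ILE,HG23,0.090
ILE,CD1,-0.270
ILE,HD11,0.090
ILE,HD12,0.090
ILE,HD13,0.090
SER,CB,0.050
SER,HB2,0.090
SER,HB3,0.090
SER,OG,-0.660
SER,HG,0.430
THR,CB,0.140
THR,HB,0.090
THR,OG1,-0.660
THR,HG1,0.430
THR,CG2,-0.270
THR,HG21,0.090
THR,HG22,0.090
THR,HG23,0.090
CYS,CB,-0.110
CYS,HB2,0.090
CYS,HB3,0.090
CYS,SG,-0.230
CYS,HG,0.160
MET,CB,-0.180
MET,HB2,0.090
MET,HB3,0.090
MET,CG,-0.140
MET,HG2,0.090
MET,HG3,0.090
MET,SD,-0.090
MET,CE,-0.220
MET,HE1,0.090
MET,HE2,0.090
MET,HE3,0.090
PHE,CB,-0.180
PHE,HB2,0.090
PHE,HB3,0.090
PHE,CG,0.000
PHE,CD1,-0.115
PHE,HD1,0.115
PHE,CD2,-0.115
PHE,HD2,0.115
PHE,CE1,-0.115
PHE,HE1,0.115
PHE,CE2,-0.115
PHE,HE2,0.115
PHE,CZ,-0.115
PHE,HZ,0.115
TYR,CB,-0.180
TYR,HB2,0.090
TYR,HB3,0.090
TYR,CG,0.000
TYR,CD1,-0.115
TYR,HD1,0.115
TYR,CD2,-0.115
TYR,HD2,0.115
TYR,CE1,-0.115
TYR,HE1,0.115
TYR,CE2,-0.115
TYR,HE2,0.115
TYR,CZ,0.110
TYR,OH,-0.540
TYR,HH,0.430
TRP,CB,-0.180
TRP,HB2,0.090
TRP,HB3,0.090
TRP,CG,0.000
TRP,CD1,-0.115
TRP,HD1,0.115
TRP,NE1,-0.610
TRP,HE1,0.380
TRP,CD2,0.100
TRP,CE2,0.130
TRP,CE3,-0.115
TRP,HE3,0.115
TRP,CZ2,-0.115
TRP,HZ2,0.115
TRP,CZ3,-0.115
TRP,HZ3,0.115
TRP,CH2,-0.115
TRP,HH2,0.115
ASP,CB,-0.280
ASP,HB2,0.090
ASP,HB3,0.090
ASP,CG,0.620
ASP,OD1,-0.760
ASP,OD2,-0.760
GLU,CB,-0.180
GLU,HB2,0.090
GLU,HB3,0.090
GLU,CG,-0.280
GLU,HG2,0.090
GLU,HG3,0.090
GLU,CD,0.620
GLU,OE1,-0.760
GLU,OE2,-0.760
ASN,CB,-0.180
ASN,HB2,0.090
ASN,HB3,0.090
ASN,CG,0.550
ASN,OD1,-0.550
ASN,ND2,-0.620
ASN,HD21,0.320
ASN,HD22,0.300
GLN,CB,-0.180
GLN,HB2,0.090
GLN,HB3,0.090
GLN,CG,-0.180
GLN,HG2,0.090
GLN,HG3,0.090
GLN,CD,0.550
GLN,OE1,-0.550
GLN,NE2,-0.620
GLN,HE21,0.320
GLN,HE22,0.300
LYS,CB,-0.180
LYS,HB2,0.090
LYS,HB3,0.090
LYS,CG,-0.180
LYS,HG2,0.090
LYS,HG3,0.090
LYS,CD,-0.180
LYS,HD2,0.090
LYS,HD3,0.090
LYS,CE,0.210
LYS,HE2,0.050
LYS,HE3,0.050
LYS,NZ,-0.300
LYS,HZ1,0.330
LYS,HZ2,0.330
LYS,HZ3,0.330
ARG,CB,-0.180
ARG,HB2,0.090
ARG,HB3,0.090
ARG,CG,-0.180
ARG,HG2,0.090
ARG,HG3,0.090
ARG,CD,0.200
ARG,HD2,0.090
ARG,HD3,0.090
ARG,NE,-0.700
ARG,HE,0.440
ARG,CZ,0.640
ARG,NH1,-0.800
ARG,HH11,0.460
ARG,HH12,0.460
ARG,NH2,-0.800
ARG,HH21,0.460
ARG,HH22,0.460
HIS,CB,-0.090
HIS,HB2,0.090
HIS,HB3,0.090
HIS,ND1,-0.360
HIS,HD1,0.320
HIS,CG,-0.050
HIS,CE1,0.250
HIS,HE1,0.130
HIS,NE2,-0.700
HIS,CD2,0.220
HIS,HD2,0.100
HOH,O,-0.834
HOH,H1,0.417
HOH,H2,0.417
NA,NA,1.000
K,K,1.000
CL,CL,-1.000
MG,MG,2.000
ZN,ZN,2.000
CA,CA,2.000
MN,MN,2.000
FE,FE,2.000
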