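key_residue,key_atom,covalent_radius,vdw_radius,charge,donor,acceptor
*,H,0.31,1.20,0,0,0
*,D,0.31,1.20,0,0,0
*,C,0.76,1.70,0,0,0
*,N,0.71,1.55,0,1,0
*,O,0.66,1.52,0,0,1
*,S,1.05,1.80,0,0,0
*,P,1.07,1.80,0,0,0
*,F,0.57,1.47,0,0,0
*,CL,1.02,1.75,0,0,0
*,BR,1.20,1.85,0,0,0
*,I,1.39,1.98,0,0,0
*,SE,1.20,1.90,0,0,0
*,B,0.84,1.92,0,0,0
*,NA,1.66,2.27,0,0,0
*,K,2.03,2.75,0,0,0
*,MG,1.41,1.73,0,0,0
*,CA,1.76,2.31,0,0,0
*,ZN,1.22,2.01,0,0,0
*,FE,1.32,2.04,0,0,0
*,MN,1.39,2.05,0,0,0
*,CU,1.32,1.96,0,0,0
*,CO,1.26,2.00,0,0,0
*,NI,1.24,1.97,0,0,0
ASP,OD1,0.66,1.52,-1,0,1
ASP,OD2,0.66,1.52,-1,0,1
GLU,OE1,0.66,1.52,-1,0,1
GLU,OE2,0.66,1.52,-1,0,1
LYS,NZ,0.71,1.55,1,1,0
ARG,NE,0.71,1.55,1,1,0
ARG,NH1,0.71,1.55,1,1,0
ARG,NH2,0.71,1.55,1,1,0
HIS,ND1,0.71,1.55,0,1,1
HIS,NE2,0.71,1.55,0,1,1
SER,OG,0.66,1.52,0,1,1
THR,OG1,0.66,1.52,0,1,1
TYR,OH,0.66,1.52,0,1,1
ASN,OD1,0.66,1.52,0,0,1
ASN,ND2,0.71,1.55,0,1,0
GLN,OE1,0.66,1.52,0,0,1
GLN,NE2,0.71,1.55,0,1,0
TRP,NE1,0.71,1.55,0,1,0
PRO,N,0.71,1.55,0,0,0
ZN,ZN,1.22,2.01,1,0,0
NA,NA,1.66,2.27,1,0,0
K,K,2.03,2.75,1,0,0
MG,MG,1.41,1.73,1,0,0
CA,CA,1.76,2.31,1,0,0
FE,FE,1.32,2.04,1,0,0
FE2,FE,1.32,2.04,1,0,0
MN,MN,1.39,2.05,1,0,0
CU,CU,1.32,1.96,1,0,0
CO,CO,1.26,2.00,1,0,0
NI,NI,1.24,1.97,1,0,0
CL,CL,1.02,1.75,-1,0,1
BR,BR,1.20,1.85,-1,0,1
IOD,I,1.39,1.98,-1,0,1
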