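CC(=O)Oc1ccccc1C(=O)O
Cn1cnc2c1c(=O)n(C)c(=O)n2C
CC(C)Cc1ccc(cc1)C(C)C(=O)O
CC(=O)Nc1ccc(O)cc1
COc1ccc2cc(ccc2c1)C(C)C(=O)O
CN1CCCC1c1cccnc1
CCOC(=O)c1ccc(N)cc1
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
CC(C)NCC(O)COc1cccc2ccccc12
CCN(CC)CC(=O)Nc1c(C)cccc1C
CCN(CC)CCOC(=O)c1ccc(N)cc1
O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1
CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O
CN(C)C(=N)NC(=N)N
Nc1ccc(cc1)S(N)(=O)=O
CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc12
CN(C)CCCN1c2ccccc2CCc2ccccc12
OC1(CCN(CCCC(=O)c2ccc(F)cc2)CC1)c1ccc(Cl)cc1
CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1
NC(=O)c1cccnc1
NNC(=O)c1ccncc1
CC(=O)Nc1nnc(s1)S(N)(=O)=O
OC(=O)C=Cc1ccc(O)c(O)c1
O=CC=Cc1ccccc1
COc1cc(C=O)ccc1O
OC(=O)c1ccccc1O
NC(=O)c1ccccc1
CNCC(O)c1cccc(O)c1
CNC(C)C(O)c1ccccc1
CC(N)Cc1ccccc1
COc1cc(CCN)cc(OC)c1OC
NCCc1ccc(O)c(O)c1
NCCc1c[nH]c2ccc(O)cc12
NC(Cc1c[nH]c2ccccc12)C(=O)O
NC(Cc1ccc(O)cc1)C(=O)O
NC(Cc1ccccc1)C(=O)O
NCCc1c[nH]cn1
COc1ccc2[nH]cc(CCNC(C)=O)c2c1
CC(C(=O)O)c1cccc(c1)C(=O)c1ccccc1
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl
COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC
OCC(NC(=O)C(Cl)Cl)C(O)c1ccc(cc1)[N+](=O)[O-]
Cc1ncc(n1CCO)[N+](=O)[O-]
NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O
Cc1cc(no1)NS(=O)(=O)c2ccc(N)cc2
Clc1ccccc1C(=O)Nc1ccc(cc1)C(=O)O
CCOc1ccc(NC(C)=O)cc1
Cc1ccc(cc1)S(=O)(=O)N
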