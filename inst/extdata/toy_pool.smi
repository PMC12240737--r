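# Curated toy molecule pool for the packaged test world.
# Drug-like molecules plus deliberate constraint violators (3-, 4-, 7-, 8-membered
# rings and alert-bearing structures). All entries are valid, canonicalizable SMILES.
CC(C)Cc1ccc(C(C)C(=O)O)cc1
CC(=O)Oc1ccccc1C(=O)O
CC(=O)Nc1ccc(O)cc1
Cn1c(=O)c2c(ncn2C)n(C)c1=O
CC(C)NCC(O)COc1ccccc1
c1ccc2[nH]ccc2c1
c1ccc2ncccc2c1
c1ccncc1
c1ccc(-c2ccccc2)cc1
Cc1ccccc1C
COc1ccc(CCN)cc1
NCCc1c[nH]c2ccccc12
OCC1OC(O)C(O)C(O)C1O
CC(N)Cc1ccccc1
CN1CCC(c2ccccc2)CC1
O=C(O)c1ccccc1O
Nc1ccc(S(N)(=O)=O)cc1
CCN(CC)CCNC(=O)c1ccc(N)cc1
Cc1ccc(C)c(O)c1
COc1cc2ccnc(C)c2cc1OC
CC(=O)Nc1nnc(S(N)(=O)=O)s1
O=c1[nH]cnc2[nH]cnc12
Nc1ncnc2[nH]cnc12
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1
CN(C)CCc1c[nH]c2ccc(O)cc12
OC(c1ccccc1)c1ccccc1
O=C(Nc1ccccc1)c1ccccc1
CCOC(=O)c1ccccc1N
Cc1ncc(CO)c(CO)c1O
c1cnc2[nH]ccc2c1
Oc1ccc(Cl)cc1
Cc1cc(C)nc(N)n1
Nc1ccccc1C(=O)O
CC(O)c1ccc(O)cc1
COc1ccccc1OC
CCc1ccc(O)cc1
CN1CCN(c2ccccc2)CC1
O=C1CCCCC1
OC1CCCCC1
C1CCNCC1
C1CCOCC1
CC1CCC(C)CC1
c1ccc(N2CCOCC2)cc1
Cc1cccc(C)c1NC(=O)CN(CC)CC
COC(=O)c1ccc(O)cc1
CC(C)(C)c1ccc(O)cc1
Nc1ccc(C(=O)O)cc1
O=C(O)Cc1ccccc1
CCOc1ccc(NC(C)=O)cc1
Cn1cnc2c1c(=O)n(C)c(=O)n2C
OCc1ccccc1
NC(Cc1ccc(O)cc1)C(=O)O
NC(Cc1c[nH]c2ccccc12)C(=O)O
CC(C)c1ccccc1O
Oc1ccc2ccccc2c1
CN(C)c1ccc(C=Cc2ccccn2)cc1
Cc1ccc(S(=O)(=O)Nc2ccccn2)cc1
Nc1nc2ccccc2s1
c1ccc2sc(N3CCNCC3)nc2c1
Cc1ccc2nc(N)sc2c1
O=C(O)c1cccnc1
Cc1cccnc1C
Nc1ccncc1
O=C(Cc1ccccc1)Nc1ccccc1
CC(C)(C)OC(=O)NC1CCNCC1
O=S(=O)(c1ccccc1)N1CCCC1
Cc1nnc(C)s1
COc1ccc(C(C)=O)cc1
CC(=O)c1ccc(N)cc1
Oc1ccccc1c1ccccc1
CCN1CCCC1=O
O=C1NC(=O)c2ccccc21
CC1=CC(=O)CC(C)(C)C1
Cc1occc1C(=O)Nc1ccccc1
CN1CCCC1c1cccnc1
COc1cccc(OC)c1
CNC(=O)c1ccccc1
Cc1ccnc(C)c1
CCOC(=O)C1CCN(C)CC1
Oc1cccc2cccnc12
CC(C)N1CCNCC1
Fc1ccc(-c2ccccc2)cc1
Cc1ccc(N2CCNCC2)cc1
COc1ccc(N)cc1
Clc1cccc(N2CCNCC2)c1
CC(=O)N1CCN(c2ccccc2)CC1
Cc1nc2ccccc2[nH]1
c1ccc(CN2CCCCC2)cc1
OCCN1CCN(c2ccccc2)CC1
C1CC1
C1CCC1
C1CCCCCC1
C1CCCCCCC1
CC1CC1
OC1CCC1
C1CC1c1ccccc1
C1CCCCC1C1CCCCCC1
O=C1CCCCCC1
NC1CC1
C1CCCC1C1CC1
O=[N+]([O-])c1ccccc1
O=[N+]([O-])c1ccc(O)cc1
O=Cc1ccccc1
O=Cc1ccc(O)cc1
SCc1ccccc1
Sc1ccccc1
C1CO1
CC1CO1
ClCCc1ccccc1
BrCCCc1ccccc1
OOc1ccccc1
CC(=O)C=Cc1ccccc1
c1ccc(N=Nc2ccccc2)cc1
NNc1ccccc1
O=C(C=C)Nc1ccccc1
CP(C)(=O)O
C#Cc1ccccc1
O=[N+]([O-])c1ccc(C=O)cc1
NN=Cc1ccccc1
CSSC
O=C(O)C(Cl)c1ccccc1
[N-]=[N+]=NCc1ccccc1
CCOS(C)(=O)=O
CC(=O)OC(C)=O
C[N+](C)(C)Cc1ccccc1
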