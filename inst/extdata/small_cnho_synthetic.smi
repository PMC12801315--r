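# Synthetic small-molecule library: C/H/N/O only, <= 10 heavy atoms.
# Curated enumeration of common functional-group chemotypes.
# One canonical SMILES per line.
C
CC
C(C)C
C(CC)C
C(C)(C)C
C(CC)CC
C(CC)(C)C
C(C)(C)(C)C
C(CCC)CC
C(CCCC)CC
C1CC1
C1CCC1
C1CCCC1
C1CCCCC1
C1(CCCCC1)C
C1CCCCCC1
CO
C(C)O
C(CO)C
C(C)(C)O
C(CCO)C
C(CC)(C)O
C(C)(C)(C)O
C(CCCO)C
C(CO)O
C(CO)CO
C(CO)(C)O
C(CO)(CO)O
C1(CCCCC1)O
C1(CCCCC1)CO
C(CO)(C)C
C(CCO)CO
COC
C(C)OC
C(C)OCC
C(COC)OC
C1CCCO1
C1CCCCO1
C1COCCO1
C1(CCCO1)C
C=O
C(C)=O
C(CC)=O
C(CCC)=O
C(C(C)C)=O
C(CCCC)=O
C(CO)=O
C(C)(C)=O
C(CC)(C)=O
C(CC)(CC)=O
C(CCC)(C)=O
C(C(C)C)(C)=O
C1(CCCCC1)=O
C1(CCCC1)=O
C(CC(C)C)(C)=O
C(CO)(C)=O
C(=O)O
C(C)(=O)O
C(CC)(=O)O
C(CCC)(=O)O
C(C(C)C)(=O)O
C(CCCC)(=O)O
C(CO)(=O)O
C(CCC(=O)O)(=O)O
C(CO)(C)(C)C
C(=O)OC
C(C)(=O)OC
C(C)(=O)OCC
C(CC)(=O)OC
C(=O)OCC
C(C)(=O)OC(C)C
C1(CCCO1)=O
C1(CCCCO1)=O
C(CCC)(=O)OC
CN
C(C)N
C(CN)C
C(C)(C)N
CNC
CN(C)C
C(C)NCC
C(CN)(C)C
C1CCCN1
C1CCCCN1
C1CCCCN1C
C1CNCCN1
C1COCCN1
C(CN)N
C(CO)N
C(CCO)N
C(N)=O
C(C)(N)=O
C(C)(NC)=O
C(C)(N(C)C)=O
C(CC)(N)=O
C(N)(N)=O
C(C)(NCC)=O
C(C)#N
C(CC)#N
C(C(C)C)#N
C(CC#N)#N
C=C
C(=C)C
C(=CC)C
C(=C)(C)C
C(C=C)=C
C(=C)CO
C1=CCCCC1
C1=CCCC1
C#C
C(#C)C
C(#CC)C
C(C=C)#N
C(C=O)=C
C(=CC=O)C
c1ccccc1
Cc1ccccc1
C(C)c1ccccc1
Cc1c(C)cccc1
Cc1cc(C)ccc1
Cc1ccc(C)cc1
c1(ccccc1)O
COc1ccccc1
c1(ccccc1)N
CNc1ccccc1
C(c1ccccc1)=O
C(C)(c1ccccc1)=O
C(c1ccccc1)(=O)O
C(c1ccccc1)#N
Cc1ccc(cc1)O
Cc1ccc(cc1)N
c1(ccc(cc1)O)O
C(c1ccccc1)O
C(c1ccccc1)N
c1(cc(ccc1)O)O
Cc1ccc(cc1)OC
c1ccccn1
Cc1ccccn1
Cc1cnccc1
Cc1ccncc1
C(C)c1ccccn1
c1ccco1
Cc1ccco1
c1ccc[nH]1
Cc1ccc[nH]1
c1cnccn1
c1ccnnc1
Cc1ccnc(C)c1
c12c(cccc1)[nH]cc2
c12c(cccc1)occ2
C(c1ccco1)=O
Cc1c(C)occ1
c1(ccccn1)N
c1(ccccn1)O
Cc1cnccn1
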